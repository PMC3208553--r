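# Monte Carlo per-cell event simulator: makes gating, fitting and parameter
# recovery testable without any real cytometry data.

#' Simulate per-cell flow-cytometry events
#'
#' Draws one event per cell under the generative model: the hit count
#' `nHits ~ Poisson(m)` (untruncated — truncation is a fitting-side
#' approximation only); `kInternalized` counts independent per-hit successes
#' at probability `p`; the uptake-channel log fluorescence is normal with
#' mean `logMean(neg) + kInternalized * alpha * logSd(neg)` and SD
#' `logSd(neg)`; a cell retaining at least one adsorbed (non-internalized)
#' target is adsorption-marker positive and its marker log fluorescence is
#' shifted up by `markerShift` marker log-SDs. Fully reproducible from the
#' config's seed.
#'
#' @param config a [SimConfig()].
#' @return `data.frame` with one row per cell: `nHits, kInternalized,
#'   uptakeLogFi, markerLogFi, adsorptionPositive`.
#' @examples
#' neg <- NegativeControlStats(4.57 * log(10), 0.29 * log(10), 10000L)
#' ev <- simulateCells(SimConfig(ParamPoint(2.17, 0.739, 2.53), neg,
#'                               nCells = 1000, seed = 1))
#' mean(ev$adsorptionPositive)   # near 1 - exp(-m (1 - p)) = 0.432
#' @export
simulateCells <- function(config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(config@seed)
  truth <- config@truth
  neg <- config@neg
  n <- rpois(config@nCells, truth@m)
  k <- rbinom(config@nCells, n, truth@p)
  adsPos <- (n - k) >= 1L
  upt <- rnorm(config@nCells,
               mean = neg@logMean + k * truth@alpha * neg@logSd,
               sd = neg@logSd)
  mk <- rnorm(config@nCells,
              mean = config@markerNegLogMean +
                as.numeric(adsPos) * config@markerShift * config@markerLogSd,
              sd = config@markerLogSd)
  data.frame(nHits = n, kInternalized = k, uptakeLogFi = upt,
             markerLogFi = mk, adsorptionPositive = adsPos)
}

#' Simulate a negative-control (macrophages-only) well
#'
#' All events have zero hits; the uptake channel follows the negative-control
#' distribution and the marker channel its negative component.
#'
#' @param neg a [NegativeControlStats()].
#' @param nCells number of events.
#' @param seed mandatory RNG seed.
#' @param markerNegLogMean,markerLogSd marker-negative log-normal parameters.
#' @return Same event `data.frame` as [simulateCells()].
#' @export
simulateNegativeControl <- function(neg, nCells, seed,
                                    markerNegLogMean = log(50),
                                    markerLogSd = 0.4) {
  stopifnot(is(neg, "NegativeControlStats"))
  nCells <- as.integer(nCells)
  if (is.na(nCells) || nCells < 1L)
    .configError("'nCells' must be a single integer >= 1")
  if (missing(seed) || length(seed) != 1L || is.na(seed))
    .configError("'seed' is mandatory (no silent nondeterminism)")
  set.seed(as.integer(seed))
  k <- integer(nCells)
  upt <- rnorm(length(k), mean = neg@logMean, sd = neg@logSd)
  mk <- rnorm(length(k), mean = markerNegLogMean, sd = markerLogSd)
  data.frame(nHits = k, kInternalized = k, uptakeLogFi = upt,
             markerLogFi = mk, adsorptionPositive = rep(FALSE, length(k)))
}

#' Quadrant fractions of simulated events
#'
#' Applies a [GateSet()] to in-memory simulated events exactly as
#' [observedQuadrants()] does to ingested data (thresholds are in the log
#' domain): `q23` is the marker-positive fraction, `q1` the marker-negative
#' fraction above the uptake gate.
#'
#' @param events event `data.frame` from [simulateCells()].
#' @param gates a [GateSet()].
#' @return A [QuadrantFractions()].
#' @export
eventsToObserved <- function(events, gates) {
  stopifnot(is.data.frame(events), is(gates, "GateSet"))
  if (nrow(events) == 0L) .dataError("no events to gate")
  markerPos <- events$markerLogFi > gates@markerThreshold
  QuadrantFractions(
    q1 = mean(!markerPos & events$uptakeLogFi > gates@uptakeThreshold),
    q23 = mean(markerPos))
}

#' Write simulated events as a linear-scale CSV export
#'
#' Exponentiates the log fluorescences to linear scale values (the format
#' cytometry software exports) and writes a headered CSV with columns
#' `uptake_fi, marker_fi, n_hits, k_internalized`. A positive
#' `baselineOffset` is subtracted from both channels to emulate instrument
#' baseline correction producing negative scale values, exercising the
#' [baselineCorrect()] path on ingestion.
#'
#' @param events event `data.frame` from [simulateCells()].
#' @param path output CSV path.
#' @param baselineOffset constant subtracted from both linear channels
#'   (default 0).
#' @return `path`, invisibly.
#' @export
writeEventCsv <- function(events, path, baselineOffset = 0) {
  stopifnot(is.data.frame(events))
  out <- data.frame(uptake_fi = exp(events$uptakeLogFi) - baselineOffset,
                    marker_fi = exp(events$markerLogFi) - baselineOffset,
                    n_hits = events$nHits,
                    k_internalized = events$kInternalized)
  write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
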