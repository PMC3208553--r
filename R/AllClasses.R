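# S4 containers shared across the forward model, the parameter-space scan,
# the event simulator and the flow-export ingestion layer.

.configError <- function(msg) {
  stop(errorCondition(msg, class = c("phagoscan_config_error", "error",
                                     "condition")))
}

.dataError <- function(msg) {
  stop(errorCondition(msg, class = c("phagoscan_data_error", "error",
                                     "condition")))
}

.scalarNum <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## ---------------------------------------------------------------------------
## NegativeControlStats
## ---------------------------------------------------------------------------

#' Negative-control fluorescence statistics
#'
#' Log-domain mean and standard deviation of the uptake channel of a
#' macrophages-only (no fluorescent targets) control. The log-mean defines the
#' horizontal quadrant gate (half of the control population lies above it) and
#' the log-SD is the unit in which the per-internalized-target shift `alpha`
#' is expressed. Natural logs are used internally; because `alpha` and the
#' gate position are SD-normalized, the model is invariant to the log base.
#'
#' @slot logMean numeric(1), mean of log-transformed uptake fluorescence.
#' @slot logSd numeric(1), SD of log-transformed uptake fluorescence (> 0).
#' @slot nEvents integer(1), number of control events the statistics summarize.
#' @export
setClass("NegativeControlStats",
  representation(logMean = "numeric", logSd = "numeric", nEvents = "integer"),
  validity = function(object) {
    msg <- character()
    if (!.scalarNum(object@logMean))
      msg <- c(msg, "'logMean' must be a single finite number")
    if (!.scalarNum(object@logSd) || object@logSd <= 0)
      msg <- c(msg, "'logSd' must be a single positive number")
    if (length(object@nEvents) != 1L || is.na(object@nEvents) ||
        object@nEvents < 1L)
      msg <- c(msg, "'nEvents' must be a single integer >= 1")
    if (length(msg)) msg else TRUE
  })

#' @rdname NegativeControlStats-class
#' @param logMean,logSd,nEvents see slots.
#' @return A `NegativeControlStats` object.
#' @examples
#' NegativeControlStats(logMean = 4.57 * log(10), logSd = 0.29 * log(10),
#'                      nEvents = 10000L)
#' @export
NegativeControlStats <- function(logMean, logSd, nEvents = 1L) {
  new("NegativeControlStats", logMean = as.numeric(logMean),
      logSd = as.numeric(logSd), nEvents = as.integer(nEvents))
}

#' @rdname NegativeControlStats-class
#' @param x a `NegativeControlStats`.
#' @export
setMethod("logMean", "NegativeControlStats", function(x) x@logMean)

#' @rdname NegativeControlStats-class
#' @export
setMethod("logSd", "NegativeControlStats", function(x) x@logSd)

#' @rdname NegativeControlStats-class
#' @export
setMethod("nEvents", "NegativeControlStats", function(x) x@nEvents)

setMethod("show", "NegativeControlStats", function(object) {
  cat(sprintf(
    "NegativeControlStats: logMean = %.4f, logSd = %.4f (n = %d events)\n",
    object@logMean, object@logSd, object@nEvents))
})

## ---------------------------------------------------------------------------
## ParamPoint
## ---------------------------------------------------------------------------

#' One point in (m, p, alpha) parameter space
#'
#' `m` is the functional target-to-macrophage ratio governing the Poisson
#' distribution of adsorption hits; `p` the probability that any single
#' adsorbed target is internalized (independent across targets on one cell);
#' `alpha` the mean log-fluorescence shift per internalized target, in units
#' of the negative control's log-SD. The forward model tolerates any `m > 0`
#' and `alpha >= 0`; the scan bounds (`m < 6.5`, `alpha <= 4.5`) are enforced
#' by [GridSpec()].
#'
#' @slot m numeric(1), functional ratio (> 0).
#' @slot p numeric(1), per-target phagocytosis probability in \[0, 1\].
#' @slot alpha numeric(1), per-target shift in negative-control log-SD units
#'   (>= 0).
#' @export
setClass("ParamPoint",
  representation(m = "numeric", p = "numeric", alpha = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!.scalarNum(object@m) || object@m <= 0)
      msg <- c(msg, "'m' must be a single number > 0")
    if (!.scalarNum(object@p) || object@p < 0 || object@p > 1)
      msg <- c(msg, "'p' must be a single number in [0, 1]")
    if (!.scalarNum(object@alpha) || object@alpha < 0)
      msg <- c(msg, "'alpha' must be a single number >= 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname ParamPoint-class
#' @param m,p,alpha see slots.
#' @return A `ParamPoint` object.
#' @examples
#' ParamPoint(m = 2.17, p = 0.739, alpha = 2.53)
#' @export
ParamPoint <- function(m, p, alpha) {
  new("ParamPoint", m = as.numeric(m), p = as.numeric(p),
      alpha = as.numeric(alpha))
}

#' @rdname ParamPoint-class
#' @param x a `ParamPoint`.
#' @export
setMethod("functionalRatio", "ParamPoint", function(x) x@m)

#' @rdname ParamPoint-class
#' @export
setMethod("phagoProb", "ParamPoint", function(x) x@p)

#' @rdname ParamPoint-class
#' @export
setMethod("fluorShift", "ParamPoint", function(x) x@alpha)

setMethod("show", "ParamPoint", function(object) {
  cat(sprintf("ParamPoint: m = %g, p = %g, alpha = %g\n",
              object@m, object@p, object@alpha))
})

## ---------------------------------------------------------------------------
## QuadrantFractions
## ---------------------------------------------------------------------------

#' Quadrant fractions from a two-channel phagocytosis assay
#'
#' `q1` is the fraction of cells that are adsorption-marker negative with
#' uptake fluorescence above the negative-control log-mean gate;
#' `q23` is the fraction of adsorption-marker-positive cells (quadrants 2 and
#' 3 pooled — the model never splits them). The remainder `1 - q1 - q23` is
#' the marker-negative, below-gate population.
#'
#' @slot q1 numeric(1), >= 0.
#' @slot q23 numeric(1), >= 0; `q1 + q23 <= 1`.
#' @export
setClass("QuadrantFractions",
  representation(q1 = "numeric", q23 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!.scalarNum(object@q1) || object@q1 < 0)
      msg <- c(msg, "'q1' must be a single number >= 0")
    if (!.scalarNum(object@q23) || object@q23 < 0)
      msg <- c(msg, "'q23' must be a single number >= 0")
    if (length(msg) == 0L && object@q1 + object@q23 > 1 + 1e-9)
      msg <- c(msg, "'q1' + 'q23' must not exceed 1")
    if (length(msg)) msg else TRUE
  })

#' @rdname QuadrantFractions-class
#' @param q1,q23 see slots.
#' @return A `QuadrantFractions` object.
#' @export
QuadrantFractions <- function(q1, q23) {
  new("QuadrantFractions", q1 = as.numeric(q1), q23 = as.numeric(q23))
}

#' @rdname QuadrantFractions-class
#' @param x a `QuadrantFractions`.
#' @export
setMethod("q1", "QuadrantFractions", function(x) x@q1)

#' @rdname QuadrantFractions-class
#' @export
setMethod("q23", "QuadrantFractions", function(x) x@q23)

setMethod("show", "QuadrantFractions", function(object) {
  cat(sprintf("QuadrantFractions: Q1 = %.4f, Q(2+3) = %.4f (rest %.4f)\n",
              object@q1, object@q23, 1 - object@q1 - object@q23))
})

## ---------------------------------------------------------------------------
## GridSpec
## ---------------------------------------------------------------------------

#' Parameter-space grid for the residual scan
#'
#' Ordered axis values for `p`, `alpha` and `m`, plus the Poisson truncation
#' `nMax`. Axes must be strictly increasing and lie within the model's scan
#' bounds: `p` in \[0, 1\], `0 < alpha <= 4.5`, `0 < m < 6.5`. The `m` bound
#' guards the truncation: at `nMax = 12` the cumulative Poisson mass for
#' `n <= 12` stays above 0.98 only for `m < 6.5`. A warning is issued for
#' axis resolutions below p = 0.04 or alpha = 0.1, where scans develop
#' multiple narrowly spaced local minima (ripples) that carry no information.
#'
#' @slot pValues,alphaValues,mValues numeric, strictly increasing axis values.
#' @slot nMax integer(1), Poisson truncation (default 12).
#' @export
setClass("GridSpec",
  representation(pValues = "numeric", alphaValues = "numeric",
                 mValues = "numeric", nMax = "integer"),
  validity = function(object) {
    msg <- character()
    chkAxis <- function(v, name) {
      if (length(v) < 1L || anyNA(v) || any(!is.finite(v)))
        return(sprintf("axis '%s' must be non-empty and finite", name))
      if (length(v) > 1L && any(diff(v) <= 0))
        return(sprintf("axis '%s' must be strictly increasing", name))
      NULL
    }
    msg <- c(msg, chkAxis(object@pValues, "p"),
             chkAxis(object@alphaValues, "alpha"),
             chkAxis(object@mValues, "m"))
    if (length(msg) == 0L) {
      if (any(object@pValues < 0) || any(object@pValues > 1))
        msg <- c(msg, "axis 'p' exceeds model bounds [0, 1]")
      if (any(object@alphaValues <= 0) || any(object@alphaValues > 4.5))
        msg <- c(msg, "axis 'alpha' exceeds model bounds (0, 4.5]")
      if (any(object@mValues <= 0) || any(object@mValues >= 6.5))
        msg <- c(msg, "axis 'm' exceeds model bounds (0, 6.5)")
    }
    if (length(object@nMax) != 1L || is.na(object@nMax) || object@nMax < 1L)
      msg <- c(msg, "'nMax' must be a single integer >= 1")
    if (length(msg)) msg else TRUE
  })

#' @rdname GridSpec-class
#' @param pValues,alphaValues,mValues,nMax see slots.
#' @return A `GridSpec` object.
#' @export
GridSpec <- function(pValues, alphaValues, mValues, nMax = 12L) {
  obj <- new("GridSpec", pValues = as.numeric(pValues),
             alphaValues = as.numeric(alphaValues),
             mValues = as.numeric(mValues), nMax = as.integer(nMax))
  if (length(obj@pValues) > 1L && min(diff(obj@pValues)) < 0.04 - 1e-9)
    warning("p-axis resolution below 0.04: expect narrowly spaced ",
            "ripple minima", call. = FALSE)
  if (length(obj@alphaValues) > 1L && min(diff(obj@alphaValues)) < 0.1 - 1e-9)
    warning("alpha-axis resolution below 0.1: expect narrowly spaced ",
            "ripple minima", call. = FALSE)
  obj
}

#' Default 20 x 20 x 20 scan grid
#'
#' Axis resolutions follow the published scan convention (p step 0.04, alpha
#' step 0.15, m step 0.0625, 20 points per axis, 8000 points in total); the
#' default ranges bracket typical fits of the assay. Shift the ranges to
#' follow local minima found at coarse resolution.
#'
#' @param pStart,alphaStart,mStart first value of each axis.
#' @param nMax Poisson truncation.
#' @return A [GridSpec()] with 20 points per axis.
#' @examples
#' g <- defaultGridSpec()
#' length(pValues(g)) * length(alphaValues(g)) * length(mValues(g))  # 8000
#' @export
defaultGridSpec <- function(pStart = 0.04, alphaStart = 0.55, mStart = 1.625,
                            nMax = 12L) {
  GridSpec(pValues = pStart + 0.04 * (0:19),
           alphaValues = alphaStart + 0.15 * (0:19),
           mValues = mStart + 0.0625 * (0:19), nMax = nMax)
}

#' @rdname GridSpec-class
#' @param x a `GridSpec`.
#' @export
setMethod("pValues", "GridSpec", function(x) x@pValues)

#' @rdname GridSpec-class
#' @export
setMethod("alphaValues", "GridSpec", function(x) x@alphaValues)

#' @rdname GridSpec-class
#' @export
setMethod("mValues", "GridSpec", function(x) x@mValues)

#' @rdname GridSpec-class
#' @export
setMethod("nMax", "GridSpec", function(x) x@nMax)

setMethod("show", "GridSpec", function(object) {
  cat(sprintf(
    "GridSpec: %d x %d x %d points (p x alpha x m), nMax = %d\n",
    length(object@pValues), length(object@alphaValues),
    length(object@mValues), object@nMax))
  cat(sprintf("  p     in [%g, %g]\n", min(object@pValues),
              max(object@pValues)))
  cat(sprintf("  alpha in [%g, %g]\n", min(object@alphaValues),
              max(object@alphaValues)))
  cat(sprintf("  m     in [%g, %g]\n", min(object@mValues),
              max(object@mValues)))
})

## ---------------------------------------------------------------------------
## GateSet
## ---------------------------------------------------------------------------

#' Quadrant gates in the log-fluorescence domain
#'
#' The horizontal (uptake) gate sits at the negative control's log-mean, so
#' that 50\% of the control population falls in quadrant 1; the vertical
#' (adsorption-marker) gate at a high quantile of the control's marker
#' channel. `provenance` records which control produced the gates.
#'
#' @slot uptakeThreshold numeric(1), log-domain uptake gate.
#' @slot markerThreshold numeric(1), log-domain marker gate.
#' @slot provenance character(1), free-text origin of the gates.
#' @export
setClass("GateSet",
  representation(uptakeThreshold = "numeric", markerThreshold = "numeric",
                 provenance = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@uptakeThreshold) != 1L ||
        is.na(object@uptakeThreshold))
      msg <- c(msg, "'uptakeThreshold' must be a single number")
    if (length(object@markerThreshold) != 1L ||
        is.na(object@markerThreshold))
      msg <- c(msg, "'markerThreshold' must be a single number")
    if (length(msg)) msg else TRUE
  })

#' @rdname GateSet-class
#' @param uptakeThreshold,markerThreshold,provenance see slots.
#' @return A `GateSet` object.
#' @export
GateSet <- function(uptakeThreshold, markerThreshold,
                    provenance = "manual") {
  new("GateSet", uptakeThreshold = as.numeric(uptakeThreshold),
      markerThreshold = as.numeric(markerThreshold),
      provenance = as.character(provenance))
}

#' @rdname GateSet-class
#' @param x a `GateSet`.
#' @export
setMethod("uptakeThreshold", "GateSet", function(x) x@uptakeThreshold)

#' @rdname GateSet-class
#' @export
setMethod("markerThreshold", "GateSet", function(x) x@markerThreshold)

setMethod("show", "GateSet", function(object) {
  cat(sprintf(
    "GateSet: uptake gate %.4f, marker gate %.4f (log domain)\n  from: %s\n",
    object@uptakeThreshold, object@markerThreshold, object@provenance))
})

## ---------------------------------------------------------------------------
## EventTable
## ---------------------------------------------------------------------------

#' Per-event two-channel flow-cytometry scale values
#'
#' Linear-scale fluorescence values for the uptake (target dye) and
#' adsorption-marker channels, one element per cell event, as exported from
#' cytometry software. Instrument baseline correction can push scale values
#' below zero; [baselineCorrect()] restores positivity before the log
#' transform. `corrections` records the constants added (0 when untouched).
#'
#' @slot uptakeFi,markerFi numeric vectors of equal length, finite.
#' @slot sourceId character(1), label of the originating file or simulation.
#' @slot corrections named numeric(2), constants added to `uptake`/`marker`.
#' @export
setClass("EventTable",
  representation(uptakeFi = "numeric", markerFi = "numeric",
                 sourceId = "character", corrections = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@uptakeFi) != length(object@markerFi))
      msg <- c(msg, "channel lengths differ")
    if (anyNA(object@uptakeFi) || any(!is.finite(object@uptakeFi)) ||
        anyNA(object@markerFi) || any(!is.finite(object@markerFi)))
      msg <- c(msg, "channel values must be finite")
    if (!identical(sort(names(object@corrections)),
                   c("marker", "uptake")))
      msg <- c(msg, "'corrections' must be named c(uptake=, marker=)")
    if (length(msg)) msg else TRUE
  })

#' @rdname EventTable-class
#' @param uptakeFi,markerFi,sourceId see slots.
#' @return An `EventTable` object.
#' @export
EventTable <- function(uptakeFi, markerFi, sourceId = "unnamed") {
  new("EventTable", uptakeFi = as.numeric(uptakeFi),
      markerFi = as.numeric(markerFi), sourceId = as.character(sourceId),
      corrections = c(uptake = 0, marker = 0))
}

#' @rdname EventTable-class
#' @param x an `EventTable`.
#' @export
setMethod("uptakeFi", "EventTable", function(x) x@uptakeFi)

#' @rdname EventTable-class
#' @export
setMethod("markerFi", "EventTable", function(x) x@markerFi)

#' @rdname EventTable-class
#' @export
setMethod("sourceId", "EventTable", function(x) x@sourceId)

#' @rdname EventTable-class
#' @export
setMethod("corrections", "EventTable", function(x) x@corrections)

#' @rdname EventTable-class
#' @export
setMethod("nEvents", "EventTable", function(x) length(x@uptakeFi))

setMethod("show", "EventTable", function(object) {
  cat(sprintf("EventTable '%s': %d events\n", object@sourceId,
              length(object@uptakeFi)))
  if (any(object@corrections != 0))
    cat(sprintf("  baseline corrections: uptake +%g, marker +%g\n",
                object@corrections[["uptake"]],
                object@corrections[["marker"]]))
})

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Configuration for the per-cell event simulator
#'
#' Bundles the generative truth (a [ParamPoint()]), the negative-control
#' fluorescence statistics, the event count, a mandatory RNG seed, and the
#' adsorption-marker channel parameters. The marker channel is a
#' two-component lognormal: marker-negative cells at `markerNegLogMean`, and
#' cells retaining at least one adsorbed (non-internalized) target shifted
#' up by `markerShift` marker log-SDs — by default 6 SDs, enough to make
#' marker gating unambiguous, which is all the pooled Q2+Q3 readout needs.
#'
#' @slot truth a [ParamPoint()], the generative (m, p, alpha).
#' @slot neg a [NegativeControlStats()].
#' @slot nCells integer(1) >= 1.
#' @slot seed integer(1), mandatory RNG seed.
#' @slot markerNegLogMean,markerLogSd numeric(1), marker-negative log-normal.
#' @slot markerShift numeric(1), marker-positive shift in marker log-SD units.
#' @export
setClass("SimConfig",
  representation(truth = "ParamPoint", neg = "NegativeControlStats",
                 nCells = "integer", seed = "integer",
                 markerNegLogMean = "numeric", markerLogSd = "numeric",
                 markerShift = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@nCells) != 1L || is.na(object@nCells) ||
        object@nCells < 1L)
      msg <- c(msg, "'nCells' must be a single integer >= 1")
    if (length(object@seed) != 1L || is.na(object@seed))
      msg <- c(msg, "'seed' is mandatory (no silent nondeterminism)")
    if (!.scalarNum(object@markerNegLogMean))
      msg <- c(msg, "'markerNegLogMean' must be a single finite number")
    if (!.scalarNum(object@markerLogSd) || object@markerLogSd <= 0)
      msg <- c(msg, "'markerLogSd' must be a single positive number")
    if (!.scalarNum(object@markerShift) || object@markerShift < 0)
      msg <- c(msg, "'markerShift' must be a single number >= 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname SimConfig-class
#' @param truth,neg,nCells,seed,markerNegLogMean,markerLogSd,markerShift see
#'   slots.
#' @return A `SimConfig` object.
#' @export
SimConfig <- function(truth, neg, nCells, seed,
                      markerNegLogMean = log(50), markerLogSd = 0.4,
                      markerShift = 6) {
  new("SimConfig", truth = truth, neg = neg, nCells = as.integer(nCells),
      seed = as.integer(seed),
      markerNegLogMean = as.numeric(markerNegLogMean),
      markerLogSd = as.numeric(markerLogSd),
      markerShift = as.numeric(markerShift))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d cells, seed %d, truth m = %g, p = %g, alpha = %g\n",
    object@nCells, object@seed, object@truth@m, object@truth@p,
    object@truth@alpha))
})
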