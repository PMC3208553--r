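# Ingestion of exported scale values: baseline correction, log transform,
# negative-control statistics, quadrant gating, observed histograms.

#' Read a two-channel event CSV export
#'
#' Reads a headered CSV of linear scale values with columns `uptake_fi` and
#' `marker_fi` (extra columns are ignored), as exported from cytometry
#' software or written by [writeEventCsv()].
#'
#' @param path CSV file path.
#' @param sourceId label for provenance; defaults to the file name.
#' @return An [EventTable()].
#' @export
readEventCsv <- function(path, sourceId = basename(path)) {
  if (!file.exists(path)) .dataError(sprintf("file not found: %s", path))
  df <- read.csv(path, check.names = TRUE)
  if (!all(c("uptake_fi", "marker_fi") %in% names(df)))
    .dataError("CSV must contain columns 'uptake_fi' and 'marker_fi'")
  EventTable(uptakeFi = df$uptake_fi, markerFi = df$marker_fi,
             sourceId = sourceId)
}

#' Correct negative scale values per channel
#'
#' Instrument baseline correction can push exported scale values at or below
#' zero, breaking the log transform. For each channel of one file whose
#' minimum is <= 0, a constant equal to the magnitude of that minimum plus
#' `epsilon` is added, making every value positive; channels already
#' positive are untouched. Constants are applied per file (each
#' `EventTable`), never per batch, and are recorded in the table's
#' `corrections` slot. The operation is idempotent: a corrected table passes
#' through unchanged.
#'
#' @param table an [EventTable()].
#' @param epsilon positive offset (default 1 scale unit) keeping the
#'   corrected minimum away from zero.
#' @return The corrected [EventTable()].
#' @export
baselineCorrect <- function(table, epsilon = 1) {
  stopifnot(is(table, "EventTable"))
  if (nEvents(table) == 0L) .dataError("empty event table")
  if (!.scalarNum(epsilon) || epsilon <= 0)
    .configError("'epsilon' must be a single number > 0")
  fix <- function(v, name) {
    if (length(unique(v)) == 1L)
      .dataError(sprintf("channel '%s' has no dynamic range", name))
    if (min(v) <= 0) abs(min(v)) + epsilon else 0
  }
  cu <- fix(table@uptakeFi, "uptake")
  cm <- fix(table@markerFi, "marker")
  new("EventTable", uptakeFi = table@uptakeFi + cu,
      markerFi = table@markerFi + cm, sourceId = table@sourceId,
      corrections = c(uptake = table@corrections[["uptake"]] + cu,
                      marker = table@corrections[["marker"]] + cm))
}

#' Negative-control log-domain statistics
#'
#' Mean and SD of the natural-log-transformed uptake channel of a
#' baseline-corrected negative control. The log-mean is the geometric-mean
#' position of the control and anchors both the uptake gate and the model's
#' fluorescence reference point.
#'
#' @param control a positive-valued [EventTable()] (run
#'   [baselineCorrect()] first if the export contains non-positive values).
#' @return A [NegativeControlStats()].
#' @export
negativeStats <- function(control) {
  stopifnot(is(control, "EventTable"))
  if (nEvents(control) == 0L) .dataError("empty control table")
  if (min(control@uptakeFi) <= 0)
    .dataError("non-positive uptake values; apply baselineCorrect() first")
  lx <- log(control@uptakeFi)
  s <- sd(lx)
  if (!is.finite(s) || s == 0)
    .dataError("control uptake channel has zero log-SD")
  if (nEvents(control) < 30L)
    warning("fewer than 30 control events: SD estimate is unstable",
            call. = FALSE)
  NegativeControlStats(logMean = mean(lx), logSd = s,
                       nEvents = nEvents(control))
}

#' Derive quadrant gates from a negative control
#'
#' The horizontal (uptake) gate is placed at the control's log-mean, so 50\%
#' of the (lognormal) control population falls in quadrant 1; the vertical
#' (adsorption-marker) gate at the `markerQuantile` quantile of the
#' control's log marker channel (default 0.995, leaving at most 0.5\% of
#' control events marker-positive).
#'
#' @param control a positive-valued, baseline-corrected [EventTable()].
#' @param markerQuantile marker-gate quantile, strictly between 0.5 and 1.
#' @return A [GateSet()] with provenance recording the control and the
#'   constants used.
#' @export
deriveGates <- function(control, markerQuantile = 0.995) {
  stopifnot(is(control, "EventTable"))
  if (!.scalarNum(markerQuantile) || markerQuantile <= 0.5 ||
      markerQuantile >= 1)
    .configError("'markerQuantile' must lie strictly between 0.5 and 1")
  if (min(control@uptakeFi) <= 0 || min(control@markerFi) <= 0)
    .dataError("non-positive values; apply baselineCorrect() first")
  up <- mean(log(control@uptakeFi))
  mk <- unname(quantile(log(control@markerFi), markerQuantile))
  GateSet(uptakeThreshold = up, markerThreshold = mk,
          provenance = sprintf(
            "control '%s' (n = %d); uptake gate = log-mean; marker gate = %g quantile; corrections uptake +%g, marker +%g",
            control@sourceId, nEvents(control), markerQuantile,
            control@corrections[["uptake"]],
            control@corrections[["marker"]]))
}

#' Observed quadrant fractions of an event table
#'
#' `q23` is the fraction of events with marker fluorescence above the marker
#' gate (quadrants 2 and 3 pooled); `q1` the fraction that is
#' marker-negative with uptake fluorescence above the uptake gate. Both are
#' fractions of all events; `1 - q1 - q23` is the marker-negative,
#' below-gate remainder.
#'
#' @param table a positive-valued, baseline-corrected [EventTable()].
#' @param gates a [GateSet()].
#' @return A [QuadrantFractions()].
#' @export
observedQuadrants <- function(table, gates) {
  stopifnot(is(table, "EventTable"), is(gates, "GateSet"))
  if (nEvents(table) == 0L) .dataError("empty event table")
  if (min(table@uptakeFi) <= 0 || min(table@markerFi) <= 0)
    .dataError("non-positive values; apply baselineCorrect() first")
  markerPos <- log(table@markerFi) > gates@markerThreshold
  QuadrantFractions(
    q1 = mean(!markerPos & log(table@uptakeFi) > gates@uptakeThreshold),
    q23 = mean(markerPos))
}

#' Observed log-fluorescence histogram of the marker-negative population
#'
#' Bins the natural-log uptake fluorescence of adsorption-marker-negative
#' events into a density (integrating to 1), on the same log-FI axis
#' convention as [predictedHistogram()], for overlay export.
#'
#' @param table a positive-valued, baseline-corrected [EventTable()].
#' @param gates a [GateSet()].
#' @param breaks number of bins (>= 2) or a vector of break points passed to
#'   [graphics::hist()].
#' @return `data.frame` with columns `log_fi` (bin midpoints) and `density`.
#' @export
observedHistogram <- function(table, gates, breaks = 60L) {
  stopifnot(is(table, "EventTable"), is(gates, "GateSet"))
  if (min(table@uptakeFi) <= 0 || min(table@markerFi) <= 0)
    .dataError("non-positive values; apply baselineCorrect() first")
  if (length(breaks) == 1L && (!is.numeric(breaks) || breaks < 2))
    .configError("need at least 2 bins")
  neg <- log(table@markerFi) <= gates@markerThreshold
  if (!any(neg)) .dataError("no marker-negative events to histogram")
  h <- graphics::hist(log(table@uptakeFi)[neg], breaks = breaks,
                      plot = FALSE)
  data.frame(log_fi = h$mids, density = h$density)
}
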