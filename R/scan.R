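# Inverse problem: exhaustive residual scan over (p, alpha, m), plane
# minima, local minima along m, and nearest-neighbor matching of minima
# across experimental conditions.

#' Relative residuals between observed and predicted quadrant fractions
#'
#' `r1 = |q1 - q1_pred| / q1`, `r2 = |q23 - q23_pred| / q23`,
#' `rt = r1 + r2` — the scan's objective. Relative residuals require both
#' observed fractions to be positive; pass `absolute = TRUE` to fall back to
#' absolute residuals when an observed fraction is zero.
#'
#' @param observed a [QuadrantFractions()] with the measured fractions.
#' @param params a [ParamPoint()].
#' @param nMax Poisson truncation, >= 1.
#' @param absolute use absolute instead of relative residuals.
#' @return One-row `data.frame` with columns `m, alpha, p, q1Pred, q23Pred,
#'   r1, r2, rt`.
#' @examples
#' obs <- QuadrantFractions(q1 = 0.408, q23 = 0.427)
#' quadrantResiduals(obs, ParamPoint(2.17, 0.739, 2.53))
#' @export
quadrantResiduals <- function(observed, params, nMax = 12L,
                              absolute = FALSE) {
  stopifnot(is(observed, "QuadrantFractions"), is(params, "ParamPoint"))
  if (!absolute && (observed@q1 <= 0 || observed@q23 <= 0))
    .dataError(paste0(
      "relative residuals undefined for a zero observed fraction; ",
      "rerun with absolute = TRUE"))
  pred <- predictedQuadrants(params, nMax)
  d1 <- abs(observed@q1 - pred@q1)
  d2 <- abs(observed@q23 - pred@q23)
  r1 <- if (absolute) d1 else d1 / observed@q1
  r2 <- if (absolute) d2 else d2 / observed@q23
  data.frame(m = params@m, alpha = params@alpha, p = params@p,
             q1Pred = pred@q1, q23Pred = pred@q23,
             r1 = r1, r2 = r2, rt = r1 + r2)
}

#' Exhaustive residual scan of parameter space
#'
#' Evaluates the forward model and residuals at every grid point, ordered
#' m-major, then alpha, then p (mirroring blocks/sets/planes of the original
#' spreadsheet layout: 20 points per axis scan 8000 points). The computation
#' is vectorized over the grid but agrees exactly with per-point
#' [quadrantResiduals()].
#'
#' @param observed a [QuadrantFractions()].
#' @param grid a [GridSpec()].
#' @param absolute use absolute instead of relative residuals.
#' @return `data.frame` with one row per grid point, columns `m, alpha, p,
#'   q1Pred, q23Pred, r1, r2, rt`.
#' @examples
#' obs <- QuadrantFractions(q1 = 0.408, q23 = 0.427)
#' sc <- scanParameterSpace(obs, defaultGridSpec())
#' nrow(sc)  # 8000
#' @export
scanParameterSpace <- function(observed, grid, absolute = FALSE) {
  stopifnot(is(observed, "QuadrantFractions"), is(grid, "GridSpec"))
  if (!absolute && (observed@q1 <= 0 || observed@q23 <= 0))
    .dataError(paste0(
      "relative residuals undefined for a zero observed fraction; ",
      "rerun with absolute = TRUE"))
  pts <- expand.grid(p = grid@pValues, alpha = grid@alphaValues,
                     m = grid@mValues, KEEP.OUT.ATTRS = FALSE)
  q1p <- numeric(nrow(pts))
  q23p <- numeric(nrow(pts))
  for (n in 0:grid@nMax) {
    pmf <- dpois(n, pts$m)
    pn <- pts$p ^ n
    q1p <- q1p + pmf * pn * pnorm(n * pts$alpha)
    if (n >= 1L) q23p <- q23p + pmf * (1 - pn)
  }
  d1 <- abs(observed@q1 - q1p)
  d2 <- abs(observed@q23 - q23p)
  r1 <- if (absolute) d1 else d1 / observed@q1
  r2 <- if (absolute) d2 else d2 / observed@q23
  data.frame(m = pts$m, alpha = pts$alpha, p = pts$p,
             q1Pred = q1p, q23Pred = q23p, r1 = r1, r2 = r2, rt = r1 + r2)
}

#' Line and plane residual minima
#'
#' For every (alpha, m) line the minimum of each residual over the p axis
#' (`r1min/p1min`, `r2min/p2min`, and the objective `rtmin/ptmin` — the
#' minimum of `rt = r1 + r2` at a single point), and for every m plane the
#' overall minimum over (p, alpha). Records are re-keyed by coordinates
#' before grouping, so the result does not depend on row order. Ties break
#' toward the smallest p on a line and the smallest (alpha, then p) in a
#' plane.
#'
#' @param records scan output from [scanParameterSpace()].
#' @return List with `lines` (columns `m, alpha, r1min, p1min, r2min, p2min,
#'   rtmin, ptmin`) and `planes` (columns `m, alpha, p, rtmin, q1Pred,
#'   q23Pred`, ordered by m).
#' @export
planeMinima <- function(records) {
  .checkScanRecords(records)
  ord <- order(records$m, records$alpha, records$p)
  records <- records[ord, , drop = FALSE]
  key <- interaction(records$alpha, records$m, drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(records)), key)
  lines <- do.call(rbind, lapply(idx, function(i) {
    r <- records[i, , drop = FALSE]
    i1 <- which.min(r$r1); i2 <- which.min(r$r2); it <- which.min(r$rt)
    data.frame(m = r$m[1L], alpha = r$alpha[1L],
               r1min = r$r1[i1], p1min = r$p[i1],
               r2min = r$r2[i2], p2min = r$p[i2],
               rtmin = r$rt[it], ptmin = r$p[it])
  }))
  rownames(lines) <- NULL
  pidx <- split(seq_len(nrow(records)), records$m)
  planes <- do.call(rbind, lapply(pidx, function(i) {
    r <- records[i, , drop = FALSE]
    it <- which.min(r$rt)   # rows sorted (alpha, p): first min = smallest
    data.frame(m = r$m[1L], alpha = r$alpha[it], p = r$p[it],
               rtmin = r$rt[it], q1Pred = r$q1Pred[it],
               q23Pred = r$q23Pred[it])
  }))
  planes <- planes[order(planes$m), , drop = FALSE]
  rownames(planes) <- NULL
  list(lines = lines, planes = planes)
}

.checkScanRecords <- function(records) {
  need <- c("m", "alpha", "p", "q1Pred", "q23Pred", "r1", "r2", "rt")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    .configError(paste0("scan records must contain columns ",
                        paste(need, collapse = ", ")))
  invisible(records)
}

#' Local residual minima along the m axis
#'
#' An interior m-grid plane is a local minimum when its plane-optimal
#' residual `Rtmin(k)` is strictly lower than both m-neighbors; boundary
#' planes never qualify. A plateau (a run of exactly equal `rtmin` lower
#' than both flanking values) is reported at its lowest m, flagged with
#' `plateau = TRUE`. Minima are labeled `LM1, LM2, ...` in ascending m.
#' Multiple minima are expected: the model's `m (1 - p)` ridge makes the
#' scan degenerate along m, and the minima — not a single global optimum —
#' are the fit's deliverable.
#'
#' @param planes the `planes` element of [planeMinima()] output (or the
#'   whole list, from which it is taken).
#' @return `data.frame` with columns `label, m, alpha, p, rt, q1Pred,
#'   q23Pred, plateau`; zero rows when the profile is monotone.
#' @export
findLocalMinima <- function(planes) {
  if (is.list(planes) && !is.data.frame(planes) && !is.null(planes$planes))
    planes <- planes$planes
  if (!is.data.frame(planes) ||
      !all(c("m", "alpha", "p", "rtmin") %in% names(planes)))
    .configError("'planes' must be the plane summary of a scan")
  if (nrow(planes) < 3L)
    .configError("need at least 3 m planes to define interior local minima")
  planes <- planes[order(planes$m), , drop = FALSE]
  runs <- rle(planes$rtmin)
  starts <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  keep <- logical(length(runs$values))
  for (i in seq_along(runs$values)) {
    if (i == 1L || i == length(runs$values)) next  # boundary never qualifies
    keep[i] <- runs$values[i] < runs$values[i - 1L] &&
      runs$values[i] < runs$values[i + 1L]
  }
  at <- starts[keep]
  out <- planes[at, c("m", "alpha", "p", "rtmin", "q1Pred", "q23Pred"),
                drop = FALSE]
  names(out)[names(out) == "rtmin"] <- "rt"
  out$plateau <- runs$lengths[keep] > 1L
  out <- out[order(out$m), , drop = FALSE]
  out <- cbind(label = if (nrow(out)) paste0("LM", seq_len(nrow(out)))
               else character(0), out)
  rownames(out) <- NULL
  out
}

#' Nearest-neighbor matching of local minima across conditions
#'
#' Pairs minima from two conditions greedily by closeness on the chosen
#' axis (globally closest pair first; distance ties break toward the
#' smallest coordinate in condition A). Matching on m compares fits at a
#' constant functional ratio; matching on alpha at a constant label
#' intensity. Each pair reports the coordinate deltas (B minus A). Surplus
#' minima on the larger side are returned unmatched, never dropped.
#'
#' @param minimaA,minimaB local-minima tables from [findLocalMinima()].
#' @param axis `"m"` or `"alpha"`, the coordinate to match on.
#' @return List with `pairs` (columns `labelA, labelB, mA, mB, pA, pB,
#'   alphaA, alphaB, rtA, rtB, dM, dP, dAlpha`), `unmatchedA`, `unmatchedB`.
#' @export
matchMinima <- function(minimaA, minimaB, axis = c("m", "alpha")) {
  axis <- match.arg(axis)
  .checkMinima(minimaA, "minimaA")
  .checkMinima(minimaB, "minimaB")
  ia <- seq_len(nrow(minimaA))
  ib <- seq_len(nrow(minimaB))
  pairs <- list()
  while (length(ia) && length(ib)) {
    d <- abs(outer(minimaA[[axis]][ia], minimaB[[axis]][ib], "-"))
    best <- which(d == min(d), arr.ind = TRUE)
    # distance ties: smallest A coordinate, then smallest B coordinate
    best <- best[order(minimaA[[axis]][ia][best[, 1L]],
                       minimaB[[axis]][ib][best[, 2L]]), , drop = FALSE]
    a <- ia[best[1L, 1L]]
    b <- ib[best[1L, 2L]]
    pairs[[length(pairs) + 1L]] <- data.frame(
      labelA = minimaA$label[a], labelB = minimaB$label[b],
      mA = minimaA$m[a], mB = minimaB$m[b],
      pA = minimaA$p[a], pB = minimaB$p[b],
      alphaA = minimaA$alpha[a], alphaB = minimaB$alpha[b],
      rtA = minimaA$rt[a], rtB = minimaB$rt[b],
      dM = minimaB$m[b] - minimaA$m[a],
      dP = minimaB$p[b] - minimaA$p[a],
      dAlpha = minimaB$alpha[b] - minimaA$alpha[a])
    ia <- setdiff(ia, a)
    ib <- setdiff(ib, b)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(labelA = character(0), labelB = character(0))
  list(pairs = pairs,
       unmatchedA = minimaA[ia, , drop = FALSE],
       unmatchedB = minimaB[ib, , drop = FALSE])
}

.checkMinima <- function(x, name) {
  if (!is.data.frame(x) || nrow(x) < 1L ||
      !all(c("label", "m", "alpha", "p", "rt") %in% names(x)))
    .dataError(sprintf(
      "'%s' must be a non-empty local-minima table (label, m, alpha, p, rt)",
      name))
  invisible(x)
}

#' Attribute a between-condition shift to one model parameter
#'
#' Matches the two conditions' local minima on the m axis and decides, from
#' identifiable features of the minima, which single parameter changed.
#' Every local minimum reproduces the observed adsorption-positive fraction
#' almost exactly, so all minima of one condition share the hit-rate product
#' `lambda = m (1 - p)`; along this ridge a pure m shift shows up at
#' nearest-m pairs only as a one-grid-step slip in p. The decision rule,
#' applied in order, follows:
#'
#' 1. **p** when the median `|dP|` across matched pairs is at least 2 p-grid
#'    steps (beyond the ridge's one-step ambiguity);
#' 2. **m** when the shift in median `lambda`, converted to m-grid steps via
#'    `dLambda / (1 - p)`, is at least half a step (the observed adsorption
#'    fraction moved while p estimates did not);
#' 3. **alpha** when the median `|dAlpha|` is at least one alpha-grid step;
#' 4. **none** otherwise (conditions indistinguishable at grid resolution).
#'
#' @param minimaA,minimaB local-minima tables from [findLocalMinima()].
#' @param grid the [GridSpec()] both scans used (defines the step sizes).
#' @return List: `parameter` (`"p"`, `"alpha"`, `"m"` or `"none"`),
#'   `stepsP`, `stepsAlpha` (signed median pair deltas in grid steps),
#'   `stepsM` (m-equivalent lambda shift in grid steps), and `pairs` (all
#'   matched pairs).
#' @export
classifyShift <- function(minimaA, minimaB, grid) {
  stopifnot(is(grid, "GridSpec"))
  matched <- matchMinima(minimaA, minimaB, axis = "m")
  pairs <- matched$pairs
  if (nrow(pairs) == 0L)
    .dataError("no matched minima pairs to classify")
  step <- function(v) if (length(v) > 1L) stats::median(diff(v)) else 1
  sP <- stats::median(pairs$dP) / step(grid@pValues)
  sA <- stats::median(pairs$dAlpha) / step(grid@alphaValues)
  lamA <- stats::median(minimaA$m * (1 - minimaA$p))
  lamB <- stats::median(minimaB$m * (1 - minimaB$p))
  pBar <- stats::median(c(minimaA$p, minimaB$p))
  sM <- (lamB - lamA) /
    (max(1 - pBar, step(grid@pValues)) * step(grid@mValues))
  parameter <- if (abs(sP) >= 2) "p"
    else if (abs(sM) >= 0.5) "m"
    else if (abs(sA) >= 1) "alpha"
    else "none"
  list(parameter = parameter, stepsP = sP, stepsAlpha = sA, stepsM = sM,
       pairs = pairs)
}
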