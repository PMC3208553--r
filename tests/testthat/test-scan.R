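# Inverse problem: residuals, exhaustive scan, plane/local minima,
# nearest-neighbor matching.

test_that("residuals are relative absolute differences summing to rt", {
  pp <- figParams()
  pred <- predictedQuadrants(pp)
  # observed equal to the prediction: perfect fit
  r0 <- quadrantResiduals(pred, pp)
  expect_equal(r0$r1, 0)
  expect_equal(r0$r2, 0)
  expect_equal(r0$rt, 0)
  # prediction at half the observed q1: r1 = 0.5
  ppLow <- ParamPoint(2, 0, 1)          # predicted q1 = 0.5 exp(-2)
  obsH <- QuadrantFractions(q1 = 2 * q1(predictedQuadrants(ppLow)),
                            q23 = 0.01)
  expect_equal(quadrantResiduals(obsH, ppLow)$r1, 0.5)
  # published observed fractions vs the printed parameter set
  rT <- quadrantResiduals(QuadrantFractions(0.408, 0.427), pp)
  expect_equal(rT$r2, abs(0.427 - predictedQ23(pp)) / 0.427)
  expect_equal(rT$r2, 0.0127, tolerance = 1e-2)
  expect_equal(rT$rt, rT$r1 + rT$r2)
  # zero observed fraction: explicit error pointing at the absolute fallback
  expect_error(quadrantResiduals(QuadrantFractions(0, 0.4), pp),
               regexp = "absolute", class = "phagoscan_data_error")
  rAbs <- quadrantResiduals(QuadrantFractions(0, 0.4), pp, absolute = TRUE)
  expect_equal(rAbs$r1, q1(pred))
})

test_that("scan enumerates the full grid in m-major order and matches per-point residuals", {
  obs <- QuadrantFractions(0.408, 0.427)
  g <- defaultGridSpec()
  sc <- scanParameterSpace(obs, g)
  expect_identical(nrow(sc), 8000L)
  # m-major, then alpha, then p
  expect_equal(sc$p[1:20], pValues(g))
  expect_equal(unique(sc$m), mValues(g))
  expect_true(all(diff(match(sc$m, mValues(g))) >= 0))
  # vectorized scan agrees exactly with scalar residuals at spot points
  for (i in c(1L, 777L, 4000L, 8000L)) {
    r <- quadrantResiduals(obs, ParamPoint(sc$m[i], sc$p[i], sc$alpha[i]))
    expect_equal(sc$rt[i], r$rt, tolerance = 1e-12)
    expect_equal(sc$q1Pred[i], r$q1Pred, tolerance = 1e-12)
  }
  # 1x1x1 grid reduces to a single residual record
  g1 <- GridSpec(0.739, 2.53, 2.17)
  sc1 <- scanParameterSpace(obs, g1)
  expect_identical(nrow(sc1), 1L)
  expect_equal(sc1$rt, quadrantResiduals(obs, figParams())$rt)
})

test_that("an on-grid truth is recovered with near-zero residual", {
  truth <- ParamPoint(m = 2.1875, p = 0.72, alpha = 1.0)
  obs <- predictedQuadrants(truth)
  sc <- scanParameterSpace(obs, recoveryGrid())
  at <- which(abs(sc$m - 2.1875) < 1e-9 & abs(sc$p - 0.72) < 1e-9 &
              abs(sc$alpha - 1.0) < 1e-9)
  expect_identical(length(at), 1L)
  expect_lt(sc$rt[at], 1e-9)
})

test_that("plane minima match a brute-force minimum and nest correctly", {
  obs <- QuadrantFractions(0.45, 0.46)
  g <- GridSpec(seq(0.2, 0.8, 0.1), seq(1, 2.5, 0.5), seq(1.8, 2.6, 0.2))
  sc <- scanParameterSpace(obs, g)
  pm <- planeMinima(sc)
  # brute-force oracle per (alpha, m) line and per m plane
  for (i in seq_len(nrow(pm$lines))) {
    sub <- sc[sc$m == pm$lines$m[i] & sc$alpha == pm$lines$alpha[i], ]
    expect_equal(pm$lines$rtmin[i], min(sub$rt))
    expect_equal(pm$lines$ptmin[i], sub$p[which.min(sub$rt)])
    expect_equal(pm$lines$r1min[i], min(sub$r1))
    expect_equal(pm$lines$r2min[i], min(sub$r2))
  }
  for (i in seq_len(nrow(pm$planes))) {
    sub <- sc[sc$m == pm$planes$m[i], ]
    expect_equal(pm$planes$rtmin[i], min(sub$rt))
    # plane minimum never beats any of its line minima
    lineMins <- pm$lines$rtmin[pm$lines$m == pm$planes$m[i]]
    expect_true(all(pm$planes$rtmin[i] <= lineMins + 1e-15))
  }
  # row-order invariance: records keyed by coordinates, not position
  shuf <- sc[sample(nrow(sc)), ]
  pm2 <- planeMinima(shuf)
  expect_equal(pm2$planes, pm$planes)
  expect_equal(pm2$lines, pm$lines)
})

test_that("single-line grids reproduce the line minimum directly", {
  obs <- QuadrantFractions(0.408, 0.427)
  g <- GridSpec(seq(0.04, 0.8, 0.04), 2.53, 2.18)
  pm <- planeMinima(scanParameterSpace(obs, g))
  expect_identical(nrow(pm$lines), 1L)
  # a unique interior optimum in p at the published m and alpha
  sc <- scanParameterSpace(obs, g)
  expect_equal(pm$lines$ptmin, sc$p[which.min(sc$rt)])
  expect_gt(which.min(sc$rt), 1L)
  expect_lt(which.min(sc$rt), nrow(sc))
})

test_that("refining the p axis never worsens any plane minimum", {
  obs <- QuadrantFractions(0.45, 0.46)
  coarse <- GridSpec(seq(0.2, 0.8, 0.04), seq(1, 2.5, 0.5),
                     seq(1.8, 2.6, 0.2))
  fine <- suppressWarnings(
    GridSpec(seq(0.2, 0.8, 0.02), seq(1, 2.5, 0.5), seq(1.8, 2.6, 0.2)))
  pmC <- planeMinima(scanParameterSpace(obs, coarse))$planes
  pmF <- planeMinima(scanParameterSpace(obs, fine))$planes
  expect_true(all(pmF$rtmin <= pmC$rtmin + 1e-15))
})

test_that("local minima are strict interior minima with plateau flagging", {
  mkPlanes <- function(rt) {
    data.frame(m = seq_along(rt), alpha = 1, p = 0.5, rtmin = rt,
               q1Pred = 0.4, q23Pred = 0.4)
  }
  # strictly convex profile: exactly one local minimum
  lm1 <- findLocalMinima(mkPlanes((seq(-3, 3))^2 + 1))
  expect_identical(nrow(lm1), 1L)
  expect_identical(lm1$label, "LM1")
  expect_false(lm1$plateau)
  # strictly monotone profile: none
  expect_identical(nrow(findLocalMinima(mkPlanes(1:7))), 0L)
  # boundary values never qualify even when lowest
  expect_identical(nrow(findLocalMinima(mkPlanes(c(0.05, 0.5, 0.4)))), 0L)
  expect_identical(findLocalMinima(mkPlanes(c(0.5, 0.1, 0.4)))$m, 2L)
  # plateau reported once, at its lowest m, flagged
  lmP <- findLocalMinima(mkPlanes(c(3, 1, 1, 2, 5)))
  expect_identical(nrow(lmP), 1L)
  expect_identical(lmP$m, 2L)
  expect_true(lmP$plateau)
  # two-basin profile labels minima in ascending m
  lm2 <- findLocalMinima(mkPlanes(c(5, 1, 4, 2, 6)))
  expect_identical(lm2$label, c("LM1", "LM2"))
  expect_error(findLocalMinima(mkPlanes(c(1, 2))),
               class = "phagoscan_config_error")
})

test_that("minima matching pairs nearest neighbors and keeps surplus", {
  a <- data.frame(label = c("LM1", "LM2"), m = c(1.9, 2.2),
                  alpha = c(1.5, 1.0), p = c(0.68, 0.72),
                  rt = c(0.01, 0.005))
  # identical collections: zero deltas everywhere
  self <- matchMinima(a, a, axis = "m")
  expect_equal(self$pairs$dM, c(0, 0))
  expect_equal(self$pairs$dP, c(0, 0))
  expect_equal(self$pairs$dAlpha, c(0, 0))
  expect_identical(nrow(self$unmatchedA), 0L)
  # surplus minima are reported, not dropped
  b <- rbind(a, data.frame(label = "LM3", m = 2.6, alpha = 0.7, p = 0.76,
                           rt = 0.02))
  mb <- matchMinima(a, b, axis = "m")
  expect_identical(nrow(mb$pairs), 2L)
  expect_identical(mb$unmatchedB$label, "LM3")
  # axis choice changes the pairing deterministically
  a2 <- data.frame(label = c("A1", "A2"), m = c(1.0, 2.0),
                   alpha = c(3.0, 1.0), p = c(0.5, 0.6), rt = c(0.1, 0.1))
  b2 <- data.frame(label = c("B1", "B2"), m = c(1.1, 2.1),
                   alpha = c(1.1, 2.9), p = c(0.5, 0.6), rt = c(0.1, 0.1))
  onM <- matchMinima(a2, b2, axis = "m")$pairs
  onA <- matchMinima(a2, b2, axis = "alpha")$pairs
  expect_identical(onM$labelB[onM$labelA == "A1"], "B1")
  expect_identical(onA$labelB[onA$labelA == "A1"], "B2")
  expect_error(matchMinima(a[0, ], a), class = "phagoscan_data_error")
})
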