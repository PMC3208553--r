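# Shared fixtures: the published example parameter set, the control
# statistics it was fitted against, and an end-to-end simulate-gate-fit
# helper used by recovery and discrimination tests.

figParams <- function() ParamPoint(m = 2.17, p = 0.739, alpha = 2.53)

figNegStats <- function() {
  # log10 mean 4.57 and SD 0.29, converted to natural log
  NegativeControlStats(logMean = 4.57 * log(10), logSd = 0.29 * log(10),
                       nEvents = 10000L)
}

# 20 x 20 x 20 grid at the standard resolutions (p 0.04, alpha 0.15,
# m 0.0625) bracketing the simulation truths used in the tests
recoveryGrid <- function() {
  GridSpec(pValues = seq(0.16, 0.92, by = 0.04),
           alphaValues = seq(0.55, 3.40, by = 0.15),
           mValues = seq(1.625, 2.8125, by = 0.0625))
}

# simulate an experiment + matched control, gate, and return observed
# fractions (gates derived exactly as flow_io does from a control)
simulateObserved <- function(truth, seed, nCells = 1e5,
                             neg = figNegStats()) {
  ev <- simulateCells(SimConfig(truth, neg, nCells = nCells, seed = seed))
  ctl <- simulateNegativeControl(neg, nCells = nCells, seed = seed + 5000L)
  gates <- GateSet(uptakeThreshold = mean(ctl$uptakeLogFi),
                   markerThreshold = quantile(ctl$markerLogFi, 0.995))
  eventsToObserved(ev, gates)
}

# full inverse pipeline: simulate, gate, scan, local minima
simulateAndFit <- function(truth, seed, grid = recoveryGrid(),
                           nCells = 1e5) {
  obs <- simulateObserved(truth, seed, nCells = nCells)
  findLocalMinima(planeMinima(scanParameterSpace(obs, grid)))
}

gridStep <- function(v) median(diff(v))
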