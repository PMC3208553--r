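---
title: "A Poisson hit model for separating phagocytosis from adsorption in two-channel flow cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Poisson hit model for separating phagocytosis from adsorption in two-channel flow cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagoscan)
```

## The measurement problem

Ex vivo phagocytosis assays expose macrophages (for example PMA-activated
THP-1 cells) to fluorescently labeled targets such as DIO-labeled platelets,
and read the outcome on a flow cytometer with two channels: the target dye
(uptake channel) and a surface antibody against the target (adsorption
marker, e.g. PE-anti-CD61). The marker only stains targets still on the cell
surface, so marker-positive cells have adsorbed targets (with or without
additional internalized ones), while marker-negative cells mix true
negatives with cells whose targets were all internalized. Internalized dye
is partially quenched in the phagolysosome, so the phagocytosis-positive
population is usually not a separate peak but a bulge on the negative one.
Simple quadrant counting therefore confounds three things: how many targets
a macrophage encounters, how likely each is to be internalized, and how
bright an internalized target remains.

`phagoscan` implements a three-parameter generative model of this assay and
an exhaustive residual scan that inverts it.

## The forward model

Three parameters:

* `m` — the *functional* target:macrophage ratio. Adsorption "hits" per
  macrophage are Poisson: `P(n) = exp(-m) m^n / n!`. `m` is proportional
  to, but not equal to, the input ratio in the well.
* `p` — the probability that any single adsorbed target is internalized,
  independent across the targets on one cell.
* `alpha` — the mean log-fluorescence shift contributed by one internalized
  target, in units of the negative control's log-SD. Quenching enters the
  model only through the magnitude of `alpha`.

Three observable consequences, with the Poisson sum truncated at
`nMax = 12` (at the scan bound `m < 6.5` the retained mass is still above
0.98, which is why the bound exists):

* **Adsorption-positive fraction.**
  `Q23 = sum_{n=1}^{12} P(n) (1 - p^n)`, since a cell stays
  marker-positive unless all `n` of its hits were internalized
  (probability `p^n`). Its closed form is `1 - exp(-m (1 - p))`: only the
  product `m (1 - p)` is identified by this quadrant, which is the root of
  the scan's ridge degeneracy discussed below.
* **Quadrant-1 fraction.** The uptake gate sits at the negative control's
  log-mean. A marker-negative cell with `n` internalized targets has log
  fluorescence `N(logMean + n * alpha * logSd, logSd)` — same SD as the
  control, mean shifted by `n * alpha` SDs — so it clears the gate with
  probability `pnorm(n * alpha)`, and
  `Q1 = sum_{n=0}^{12} P(n) p^n pnorm(n * alpha)`. The `n = 0` term is
  `0.5 exp(-m)`: by construction half of the true negatives sit above the
  gate. Defining the shift in SD-normalized log units makes every formula
  independent of the log base; the package works in natural logs.
* **Predicted histogram.** The marker-negative population is a mixture of
  equally wide lognormal components at means `logMean + n * alpha * logSd`
  with weights `P(n) p^n` (renormalized over the marker-negative
  population), exportable for overlay on an observed histogram.

```{r forward}
pp <- ParamPoint(m = 2.17, p = 0.739, alpha = 2.53)
predictedQuadrants(pp)
```

This parameter set is the package's running example: a fit to a typical
DIO-platelet/THP-1 experiment whose negative control had log10 mean 4.57
and SD 0.29.

## Gating and ingestion conventions

Event tables are CSV exports of linear scale values. Instrument baseline
correction can make scale values negative; `baselineCorrect()` adds, per
channel and per file, a constant equal to the magnitude of the channel
minimum plus an epsilon (default 1 scale unit). The epsilon is the smallest
change that preserves the rule's intent while keeping the subsequent log
transform defined; correction at exactly zero is included for the same
reason. Constants are recorded on the table and echoed into gate
provenance.

`deriveGates()` places the uptake gate at the control's log-mean — the
geometric-mean position, which coincides with the median under the
control's assumed lognormality and anchors the model's `n = 0` term at
exactly one half — and the marker gate at a high quantile (default 0.995)
of the control's marker channel. The marker cut-off is a package
convention: because quadrants 2 and 3 are pooled everywhere, results are
insensitive to exactly where positives are split, and any placement that
cleanly separates the control suffices.

## The inverse problem: exhaustive scan, not optimization

`scanParameterSpace()` evaluates relative residuals
`r1 = |Q1_obs - Q1_pred| / Q1_obs`, `r2 = |Q23_obs - Q23_pred| / Q23_obs`,
`rt = r1 + r2` at every point of a `GridSpec`, ordered m-major, then alpha,
then p (the blocks/sets/planes layout of the original spreadsheet
implementation; the default 20 x 20 x 20 grid is 8000 points). Default
resolutions are p 0.04, alpha 0.15, m 0.0625; finer p or alpha grids
trigger a warning because below roughly p = 0.04 / alpha = 0.1 the residual
surface develops narrowly spaced ripple minima that carry no information.
No continuous optimizer is layered on top: the deliverable is the set of
*local* minima of the plane-optimal residual `Rtmin(k)` along m
(`findLocalMinima()`), because the `m (1 - p)` ridge makes a single global
minimum meaningless — many (m, p, alpha) combinations reproduce the two
observed fractions essentially exactly, and declaring one of them "the"
optimum would overstate what the data identify. Ties everywhere break
toward the smallest coordinate (smallest p on a line; smallest alpha, then
p, in a plane), and plateaus of equal neighboring planes are reported once,
at their lowest m, flagged.

## Comparing conditions

What rescues identifiability is experimental design: two conditions run at
the same input ratio share `m`, at the same label intensity share `alpha`.
`matchMinima()` pairs the two conditions' local minima greedily by
nearest coordinate (on m by default) and reports per-pair deltas plus any
unmatched surplus. `classifyShift()` then attributes the between-condition
change to a single parameter with an ordered rule grounded in the ridge
structure:

1. every local minimum reproduces the observed `Q23` almost exactly, so a
   genuine change in `p` moves the p-estimates of nearest-m pairs by many
   grid steps — attribute to **p** when the median `|dP|` is at least 2
   steps;
2. a pure change in `m` shifts the identifiable product
   `lambda = m (1 - p)` while nearest-m pairing absorbs it into at most a
   one-step slip in p — attribute to **m** when the median-lambda shift,
   converted to m-steps via `dLambda / (1 - p)`, reaches half a step;
3. a change in `alpha` leaves lambda untouched and moves only the alpha
   coordinates — attribute to **alpha** at a median `|dAlpha|` of one step;
4. otherwise the conditions are indistinguishable at grid resolution
   (**none**).

The thresholds are not free knobs: one p-step is exactly the ridge's
intrinsic ambiguity, and half a grid step is the resolution limit of the
scan. An earlier draft attributed by the largest delta of the single
best-fitting pair; inspection of matched-pair tables showed alpha varies
steeply along the ridge, making single-pair deltas unstable, and the rule
was replaced by the median/lambda form above.

## The simulator and what it does (not) emulate

`simulateCells()` draws per-cell events literally from the generative
assumptions: untruncated Poisson hits, per-hit Bernoulli internalization
(the literal reading of independence — the event-level mechanism is
otherwise unconstrained), normal log fluorescence shifted by
`k * alpha` SDs, and a two-component lognormal marker channel whose
positive component sits 6 marker-SDs up — marker positivity is treated as
binary downstream, so any unambiguous separation suffices. A mandatory
seed makes every table bitwise reproducible. `writeEventCsv()` exports
linear scale values and can inject a negative baseline offset to exercise
the correction path.

Simulated data therefore share the model's idealizations: no target
aggregates or doublets, no dependence of `p` on `n`, no heavy-tailed
fluorescence, no distributed phagocytic capacity across macrophages. Real
histograms typically carry more mass at high intensities than the model
predicts, and recovery results on simulated data bound what the method can
do under its own assumptions — they do not certify those assumptions in
any particular wet-lab system.

## Numerical choices and study sizes

* Truncation `nMax = 12`, configurable; grids refuse `m >= 6.5`.
* Forward model tolerates the degenerate `p = 0`, `p = 1` and `alpha = 0`;
  scan grids keep `alpha <= 4.5` because larger shifts split quadrant 1
  into visibly distinct populations that the assay does not show.
* Relative residuals require positive observed fractions; a zero fraction
  raises an explicit error pointing at the absolute-residual fallback flag.
* Recovery and discrimination checks in the test suite use 1e5 cells per
  condition and the 20 x 20 x 20 default-resolution grid — roughly the
  event count of a generous cytometry acquisition — with truth values on
  the grid. Truth `alpha` values are drawn from 0.7–1.75 SD: above about
  2.5 SD the gate-crossing probability `pnorm(n * alpha)` saturates for
  every `n >= 1`, so quadrant data contain almost no information about
  `alpha` there, and recovery of an on-grid alpha is not a meaningful
  requirement. That saturation is a model property, not a simulation
  artifact; fits of real data with large alpha should report alpha as
  "large", not as a point value.
* Discrimination scenarios change one parameter by several grid steps
  (p 0.72 to 0.88, m 2.1875 to 2.375, alpha 1.0 to 1.75); the m shift is
  kept at three steps so the ridge's one-step p-slip stays strictly
  smaller than the true change being detected.

## Known limitations

Point minima only — no bootstrap or profile uncertainty is attached to the
recovered parameters. Refinement of alpha ranges to chase minima found at
coarse resolution is user-driven (`GridSpec` is cheap to rebuild); no
automatic refinement schedule is imposed. FCS files are not parsed; the
package consumes the CSV scale-value exports that cytometry software
produces. And the model deliberately omits the mechanisms listed above as
unmodeled; where they matter, the predicted histogram overlay
(`cmdFit()`'s `histogram.csv`) is the diagnostic to inspect.
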