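---
title: "Scoring drug sensitivity on brain-slice cultures: methods and design"
author: "sliceDSS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring drug sensitivity on brain-slice cultures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sliceDSS)
```

## The measurement model

An organotypic brain-slice culture (OBSC) screen measures two things for
every drug dose: how much of the engrafted tumor dies, and how much of the
surrounding normal brain tissue dies with it. sliceDSS turns those paired
readouts into a single drug sensitivity score (DSS) on a −100..+100 scale
per drug–tumor pair.

**Tumor arm.** Each tumor focus carries a luciferase reporter, so its
assay-end bioluminescence (BLI, photons/s) is proportional to the number
of viable tumor cells. Because foci differ in starting size, each focus is
first normalized to its own day-one fluorescence, and the aggregated
treated ratio is divided by the aggregated ratio of the untreated control
group:

$$ s(d) = \frac{\overline{(\mathrm{BLI}/\mathrm{fluor})}_{\,d}}
               {\overline{(\mathrm{BLI}/\mathrm{fluor})}_{\,\mathrm{untreated}}} $$

Survival is deliberately **not capped at 1**: values above 1 mean the
treated tumor outgrew the untreated control, and the growth-acceleration
window needs exactly that information (its thresholds sit at 125% and
150%). The kill fraction is $k(d) = 1 - s(d)$ and may be negative for the
same reason. Untreated controls live at dose 0 and serve only as the
normalization denominator; they are never part of the interpolation grid.

**Toxicity arm.** Slice death is read out by propidium iodide (PI)
fluorescence, anchored between a healthy baseline and a dead control
(slices killed by ethanol/freezing):

$$ \mathrm{tox}(d) = \mathrm{clamp}\!\left(
   \frac{\overline{\mathrm{PI}}(d) - \overline{\mathrm{PI}}_\mathrm{healthy}}
        {\overline{\mathrm{PI}}_\mathrm{dead} - \overline{\mathrm{PI}}_\mathrm{healthy}},
   \, 0, 1\right) $$

The clamp reflects the physics: PI below the healthy baseline is
measurement noise, not negative death. Inverted anchors
($\mathrm{PI}_\mathrm{dead} \le \mathrm{PI}_\mathrm{healthy}$) are a hard
error rather than a silent sign flip.

Replicates are aggregated by the arithmetic mean by default (screens
report mean ± SEM); the median is available via the `aggregate` argument
for heavy-tailed plates.

## Interpolation, ECx and NR semantics

All dose-response quantities come from **linear interpolation of the
measured points** — no Hill or four-parameter-logistic fit is ever
performed, so a biphasic or non-monotone curve is scored as measured
rather than forced through a sigmoid.

Interpolation happens on a configurable axis: log10 dose for molar
concentrations (screens use log-spaced doses, so segments are equal-width
in log space) and linear dose for radiation (Gy). Both are available via
the `axis` argument; the default is chosen from the dose unit.

`computeEcx()` scans the kill series from the lowest dose upward and
reports the **first** crossing of $x/100$ — for non-monotone curves this
is the conservative (lowest-dose) potency estimate, and a curve that
touches the level along a flat segment reports the segment's lowest dose.
Two boundary cases get explicit flags instead of extrapolation:

* **NR (not reached):** the maximal kill stays below $x/100$. The dose is
  `NA`; downstream tables leave the cell empty. Any curve with < 50%
  maximal kill therefore has IC50 = NR, the standard reporting
  convention.
* **below range:** the response already meets the level at the lowest
  tested dose; the lowest dose is reported with `belowRange = TRUE`.

`computeNormalizedAuc()` is the trapezoidal area divided by the axis
length — i.e. the mean response over the tested range — which keeps AUCs
comparable across dose ranges and units and lets net growth yield
negative values. `computeSlopeAtEc50()` returns the slope of the
piecewise-linear segment containing the series' own 50% crossing (first
segment when the crossing precedes the grid, steepest segment when 50% is
never reached, 0 for a flat curve).

## The eleven therapeutic windows

Every window lives on [−1, +1]: +1 means tumor kill without tissue
toxicity, −1 means tissue toxicity without tumor kill.

| # | window | weight | definition |
|---|--------|-------:|------------|
| 1 | max kill | 10% | $\mathrm{clamp}(k(d_{max}) - \mathrm{tox}(d_{max}))$ |
| 2–6 | EC10/25/50/75/90 | 5/5/10/5/5% | kill vs toxicity at the tumor's crossing dose (below) |
| 7 | slope | 10% | bounded ratio of the slopes through each arm's EC50 |
| 8 | AUC | 35% | $\mathrm{clamp}(\mathrm{nAUC}_{kill} - \mathrm{nAUC}_{tox})$ |
| 9 | growth | 5% | +1 if max growth ≤ 125%, 0 if ≤ 150%, −1 above |
| 10 | biphasic | 5% | −1 for a biphasic shape, else +1 |
| 11 | incomplete kill | 5% | +1 if < 10% remains at top dose, 0 if ≤ 25%, −1 above |

**ECx windows.** When the tumor kill reaches $x/100$ at dose $d^*$, the
window is $\mathrm{clamp}(k(d^*) - \mathrm{tox}(d^*))$; at a true
crossing $k(d^*) = x/100$ exactly, and when the crossing precedes the
grid the observed kill and toxicity at the lowest dose are compared
instead (so a drug that clears the level everywhere is credited with its
actual kill, not the level). When the ECx is **not reached** the window
falls back to a shortfall-penalized evaluation at the top dose,
$\mathrm{clamp}(k_{max} - x/100 - \mathrm{tox}(d_{max}))$: an agent that
never attains the level must not outscore one that attains it at low
toxicity. NR fallbacks are flagged per level in the output.

**Slope window.** $(m_T - m_O)/(|m_T| + |m_O|)$ maps the slope comparison
onto the same ±1 scale. When both slopes are exactly 0 the ratio is
undefined; EC50 attainment breaks the tie: +1 when only the tumor arm
reaches its EC50, −1 when only the toxicity arm does, 0 otherwise. This
convention makes the two end-member cases come out right — an agent with
complete kill everywhere and zero toxicity scores +100 overall, and an
inert-but-lethal agent scores −1 on every tumor-vs-toxicity window — and
it reduces to 0 for genuinely symmetric flat pairs.

**Biphasic rule.** The qualitative notion "rapid killing at low doses,
limited additional killing at higher doses, substantial residual tumor"
is made operational as: max kill over the lower half of the dose grid
≥ 0.25, AND at most 0.10 additional kill beyond it, AND > 10% tumor
remaining at the top dose. All three thresholds are arguments of
`detectShape()`. Note the rule is defined **on the tested dose grid** —
its "lower half" is the first half of the tested doses — so the analytic
oracle evaluates it there too.

The DSS is exactly $100 \sum_i w_i\,\mathrm{window}_i$ with the weight
vector above (summing to 1, validated to 1e−12). Weights are overridable
but any override is echoed into the output sidecar.

## The synthetic assay generator

`simulateAssay()` is the test bed: it generates raw measurement tables in
the same CSV dialects the scoring pipeline consumes, from a Hill-form
generative model with known ground truth,

$$ s(d) = g \left[ f + \frac{1 - f}{1 + (d/\mathrm{EC}_{50})^h} \right], $$

with floor $f$, Hill coefficient $h$, and growth factor $g \ge 1$; an
optional plateau cap on the kill produces biphasic shapes, and toxicity
curves are the complement of the same saturating form. Default design
constants mirror screening practice: 6 log-spaced doses over 3 decades
centred on the tumor EC50 (linear from EC50/3 to 2·EC50 for Gy), 4 tumor
foci per dose plus 4 untreated control foci, 2 PI slices per dose (12
per assay) with 6 healthy and 6 dead anchor slices. Replicate noise is
multiplicative log-normal with mean 1 at a configurable CV
(bioluminescence is positive and right-skewed); raw values are
back-constructed so normalization recovers the closed form in
expectation, and the whole assay is byte-reproducible from its seed.

What the simulator does **not** emulate: spatial growth and invasion on
the slice, plate-position effects, shared-control correlation structure,
batch drift, or censoring at the imager's detection limit. Passing
recovery tests therefore demonstrate correctness of the scoring
arithmetic under idealized replicate noise, not robustness to every
artifact of real plates.

`oracleWindows()` provides the ground truth: the closed-form curves
evaluated on a 10^4-point dense grid, with every metric recomputed by
direct brute-force scans (first grid index at each level, mean response
for the AUC, finite-difference slope at the 50% crossing) — none of the
pipeline's interpolation code is reused. One consequence is worth
knowing: the slope window's segment-based definition converges to the
local derivative on a dense grid, which systematically exceeds the
0.6-decade chord a 6-dose screen can measure (and the steepest-segment
fallback exceeds it more). Dense-vs-sparse slope windows can therefore
differ by ~0.05–0.2 window units even on noiseless curves, worth ≤ 2 DSS
points at the slope's 10% weight; the other ten windows agree to ~0.01.
This is a resolution property of the slope definition, not an
implementation artifact.

Calibration under the default study conditions (6 doses, 4 foci, 10%
replicate CV, scenarios drawn by `randomScenario()` across typical
potency/toxicity ranges): the median |DSS − oracle DSS| over 200 seeded
assays is about 2 points, with the 90th percentile around 7–10 points —
dominated by ternary windows flipping near their thresholds, since a
140%-growth tumor sits on a step of the score. The test suite asserts
the median at ≤ 5 points; these problem sizes (200 assays, 10^4-point
oracle grids) keep the whole suite in the tens of seconds.

## Quality control

`qcBatch()` mirrors the practice of sampling a handful of untreated
slices per batch for a PI check. Each sampled slice gets a death index
(PI rescaled between the batch's healthy and dead anchors, clamped to
[0, 1]); the batch passes iff the mean index is ≤ τ_abs = 0.25 **and**,
when at least two historical batch summaries exist, within κ = 3
historical standard deviations above the historical mean. The rule is
one-sided — unusually *healthy* batches never fail. Both thresholds are
arguments and are echoed into the report; they are this package's
declared conventions, since the underlying procedure ("compare to
previous batches") is qualitative.

## Degenerate inputs and tie-breaks, collected

* No untreated controls, no healthy/dead anchors, inverted anchors,
  mixed dose units within a curve, or a dose query outside the tested
  range: hard errors, never silent repair.
* Flat segments touching an ECx level: the segment's lowest dose.
* Crossing before the lowest dose: reported at the lowest dose with a
  flag; no extrapolation in either direction.
* Both slopes zero in the slope window: EC50-attainment tie-break
  (above).
* Duplicate (drug, tumor) pairs in a score matrix: hard error; untested
  pairs stay `NA` and are preserved in every report.
* Waterfall ties: lexicographic by (drug, tumor) for reproducible
  output.

## Known limitations

* The score is a weighted sum of bounded windows, so it cannot separate
  two agents that both saturate every window; it is a screening
  prioritization, not a potency estimate.
* With 6 doses, ECx values between grid points inherit piecewise-linear
  interpolation error; the slope window inherits the chord-vs-derivative
  gap described above.
* Ternary windows make the DSS discontinuous in the data at 125%/150%
  growth and 10%/25% residual; replicate noise near those thresholds
  produces score jumps of 5–10 points.
* QC thresholds are conventions; sites with historical batch archives
  should calibrate τ_abs and κ to their own distributions.
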