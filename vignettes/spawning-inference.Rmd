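---
title: "From otolith increments to closure evaluation: the spawntrends methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From otolith increments to closure evaluation: the spawntrends methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Juvenile coral grouper collected from reef habitat carry a record of when
they were spawned: daily growth increments in their sagittal otoliths. Three
replicate counts of the increments between the settlement mark and the
otolith edge give a post-settlement age; increments between the primordium
and the settlement mark give the pelagic larval duration (PLD). Subtracting
post-settlement age and mean PLD from the collection date recovers the hatch
date of every fish that successfully recruited, and the distribution of
hatch dates over a year is a direct, demographically weighted readout of
successful spawning activity. `spawntrends` implements that inference chain
end to end — ageing QC, PLD estimation, back-calculation, age imputation for
non-aged fish, smoothed spawning curves, peak detection, environmental
screening, and the evaluation of new-moon-anchored seasonal fishery
closures — together with a synthetic-data generator that emulates the field
collections so every stage is testable offline.

```{r, eval = FALSE}
library(spawntrends)
report <- run_pipeline(default_config(seed = 1))
report
```

## Ageing and back-calculation

**Replicate-count QC.** A fish's age is accepted as the arithmetic mean of
its three replicate counts when every count lies within 10% of the median,
read inclusively: `|c - median| / median <= 0.10`. The inclusive boundary
makes the rule a closed condition, so a count at exactly 10% deviation is
accepted. Fish with fewer than three counts are flagged un-ageable rather
than errored.

**PLD.** The population PLD is the sample mean and standard deviation of
the pre-settlement increment counts over all fish whose otolith core was
read. The study system this package models has a PLD near 28 days
(27.9 ± 1.6 s.d.), and the generator uses those values as its defaults.

**Back-calculation.** Settlement date is collection date minus the
post-settlement age; hatch date is settlement date minus the mean PLD. Ages
and the mean PLD are rounded half-up to whole days before subtraction,
because calendar dates are integral and a single population-mean PLD is
subtracted from every fish. Embryonic duration (under a day in groupers) is
deliberately not subtracted. With all generator noise switched off this
arithmetic inverts the generator exactly — the round-trip identity the test
suite asserts.

## The age–length model

Only a fraction of collected fish (about 43% at study scale) are aged
directly; the rest get model-predicted ages. Recruitment cohorts are first
defined from the aged fish by a deterministic gap rule — consecutive hatch
dates more than 30 days apart split cohorts — replacing visual
identification with a reproducible procedure. The model is then

* mean: post-settlement age ~ cubic polynomial in total length + a random
  intercept per cohort (Gaussian errors);
* dispersion: log-variance linear in total length and cohort, absorbing the
  decreasing precision of increment counts in longer fish.

Fitting uses `glmmTMB` with an orthogonal polynomial basis internally;
coefficients are reported on the raw length scale by evaluating the fitted
cubic at four lengths and solving the Vandermonde system, which is exact.
Two degenerate regimes are handled explicitly: a singular cohort variance,
and near-interpolation data (residual sd ~ 0), where the log-variance MLE
diverges. Both fall back to a fixed-cohort-intercept least-squares cubic
and record the reason in the fit object.

Non-aged fish are assigned to cohorts through their collection date: each
cohort's hatch window is shifted forward by the observed range of
(post-settlement age + PLD), a date inside exactly one shifted interval maps
to that cohort, ties go to the nearest window midpoint (earlier cohort when
equidistant), and dates outside every interval are predicted from the
marginal mean over cohorts. Lengths outside the observed range ± 10% refuse
to predict — cubics diverge under extrapolation, and a refusal is more
honest than a wild number. Fish in cohorts with no aged members are dropped
and counted in the run report.

## Spawning trends

Hatch dates are tallied into 73 contiguous 5-day bins per austral year
(July 1 – June 30, so the southern-summer season is never split); the final
bin absorbs the leap day when present. Years with fewer than 30 usable fish
are excluded and reported. Each year's series is smoothed with

```
count = exp(b0 + s(time)),  errors ~ Tweedie(p, sigma^2), 1 < p < 2
```

fitted by penalized-spline REML in `mgcv`. The Tweedie family handles the
over-dispersion caused by stretches of the year with no spawning at all
(exact zeros with continuous positive mass). The power `p` is profiled on a
10-point grid over (1.05, 1.95) at a mid-grid basis dimension, the basis
dimension is then chosen by lowest AICc over a small grid (default 6, 9,
12, 16), and `p` is refined once by golden-section at the chosen dimension.
Shrinkage smooths (`select = TRUE`) let the effective degrees of freedom
fall toward zero for featureless years. A series with zero variance has no
trend to estimate and breaks REML scale estimation, so it is fitted as an
intercept-only model directly (smooth edf exactly 0).

**Peaks** are located on a daily evaluation grid as sign changes of the
finite-difference first derivative from positive to negative with negative
curvature. The first and last 10 days of each year are excluded because
spline boundary behaviour manufactures artifact turning points there, and
fitted heights below 0.5 fish per 5-day bin are not reported as peaks
(ripples in near-zero stretches). Peak-height intervals come from 200
seeded draws of the spline coefficients from their estimated Gaussian
posterior.

## Environmental drivers

Covariates are aligned to the same 5-day bins: lunar illumination is the
bin average of the illuminated fraction, computed from a low-precision
analytic ephemeris (truncated series for the solar and lunar ecliptic
longitudes; the illuminated fraction is `(1 - cos phi)/2` with `phi` the
sun–moon elongation) with a +10 h shift so evaluation instants match
Australian Eastern Standard Time; SST enters as 8-day composite averages
mapped to bin midpoints with linear interpolation across gaps up to 16 days
(longer gaps flag the bin out of the model); rainfall is summed per bin.
The ephemeris is accurate to a few tenths of a degree, which bounds the
illumination error well below 0.01 — more than enough when closures are
anchored to whole new-moon dates. One caution it inherits from the sky
rather than from the series truncation: individual lunations genuinely vary
from 29.27 to 29.83 days, so illumination exactly one mean synodic month
apart can differ by ~0.03 near the quarters where the phase curve is
steepest.

The environmental model is `count = exp(b0 + te(SST, month) + s(year))`
with Tweedie errors: a tensor-product interaction between a thin-plate SST
smooth and a cyclic month smooth (the interaction basis is a design choice;
"SST conditional on month" does not name one), plus a year-level random
effect. Candidate models adding lunar-illumination and rainfall smooths are
compared by AICc with a parsimony tie-break: among candidates within 2 AICc
of the minimum — the conventional equivalence margin — the one with fewest
terms wins. The tie-break matters because a fully penalized-out covariate
costs almost no AICc, making a strict argmin a coin flip among equivalent
models; parsimony is what turns "adds nothing" into "excluded". Pairwise
concurvity (the smooth-model analogue of collinearity) is computed for the
selected model and terms above 0.7 are flagged; flood-gauge height is
ingested but only offered as a candidate on request, since it tracks SST
and season closely enough to be flagged in exactly this way.

## Closure evaluation

New moons are found by minimizing the elongation over a 6-hourly grid with
local refinement, reported as local (+10 h) calendar dates. Closure windows
of 5 or 9 days are centred on the new moon (± 2 or ± 4 days), clipped to
the October 1 – December 31 season (92 days, which is what makes the
uniform expectations 27/92 ≈ 29% and 10/92 ≈ 11%), and placed at the
earliest moons first when fewer closures than moons are requested.
Overlapping windows merge with a warning; the *requested* policy (duration,
count) is carried separately from the realized window widths so that
boundary clipping — a new moon on October 1, say — does not invent spurious
policy levels downstream.

The capture proportion of a policy is the fraction of the year's predicted
spawning activity (the fitted smooth evaluated daily — model predictions,
not raw bin counts, though a raw mode exists for diagnostics) that falls on
closed days, with `closed_days / 92` as the uniform-spawning reference.
Capture is scale-invariant, exactly `closed_days/92` under uniform
activity, and monotone under window enlargement — all asserted as
properties.

Captured proportions across years and policies feed a Beta mixed regression
(logit link, year-level random intercept) on duration and closure count,
with boundary proportions shrunk by `(y(n-1) + 0.5)/n`. The
duration-by-count interaction is tested and dropped when non-significant;
closure-count contrasts are Tukey-adjusted through `emmeans`; the duration
effect is summarized as the 9-day : 5-day capture ratio on the response
scale, whose uniform-activity reference value is exactly 9/5 = 1.8.
All-equal proportions make the Beta precision diverge, so that degenerate
input short-circuits to an exact zero-slope result rather than pushing a
flat likelihood through the optimizer.

## The synthetic generator

The generator emulates the statistical structure of the field collections,
with defaults chosen once at study scale:

* **Spawning regime**: a mixture of truncated-normal pulses plus an
  optional uniform background. The default collection uses two pulses per
  austral year (spring, centred October 20, sd 14 d; late summer, centred
  March 1, sd 16 d; weights 1 : 0.8), giving cohorts that span roughly one
  to three months and stay separable by the 30-day gap rule, as the
  discrete cohorts in the real system were.
* **Growth**: von Bertalanffy from 23 mm at settlement toward a 650 mm
  asymptote at K = 0.001/day — near-linear (~0.6 mm/day) and strictly
  monotone over the juvenile 23–248 mm range, hence invertible for the
  age–length stage. Length noise 4 mm.
* **Ageing error**: replicate counts carry a 3% coefficient of variation —
  the within-reader CV is not reported for the real data, and 0.03 makes
  the 10% QC rule reject a small minority of fish, which is the behaviour a
  rule that exists but rarely fires implies. PLD is drawn per fish from
  N(27.9, 1.6²) days.
* **Collections**: 2–3 trips per austral year in autumn/winter; each fish
  joins the first trip after it has at least one post-settlement increment
  and is still within the 250 mm collection limit; 43% of fish per trip are
  aged (Bernoulli thinning, stratified by trip); a tenth of aged fish also
  get a pre-settlement (PLD) read.
* **Environment**: sinusoidal SST (mean 24 °C, amplitude 3.5 °C, peak
  February 1) with 0.3 °C daily noise, zero-inflated gamma rainfall, and a
  flood gauge that relaxes toward a base level with rainfall-driven
  excursions.

True hatch dates and ages ride along in `true_*` columns that analysis
stages never read; they exist so tests can score recovery.

What the generator does *not* emulate: spatial structure, larval dispersal
and parentage, year-to-year regime changes in cohort timing, satellite SST
dropout patterns, and observer-specific count biases. Passing tests
therefore demonstrate that the chain recovers the truth of a process with
this statistical shape — clean mixture pulses, stationary growth, unbiased
replicate error — not that it would be robust to every failure mode of
field data.

## Problem sizes and numerical choices

The test suite runs the chain at reduced but honest scale: single-year
series of 73 bins with 250–400 fish, age–length recovery at 50 replicates
of ~700 aged fish in 6 cohorts, peak detection at 50 seeded replicates each
of unimodal and bimodal years (smaller smoothing grids, k in {9, 12} and a
5-point power grid, are used inside replicate loops; defaults elsewhere),
and the full pipeline at 700–1763 fish over 2–3 years. Key tolerances:
QC boundary inclusive at 0.10; Tweedie power confined to (1.05, 1.95) with
refinement tolerance 0.02; AICc equivalence margin 2; concurvity flag 0.7
(below the ~0.77 a flood-height covariate typically shows against SST and
season, so that case is flagged); peak boundary exclusion 10 days; minimum
reported peak height 0.5; 30-fish minimum per fitted year.

## Known limitations

* Cohort definition is a 1-D gap rule; regimes whose pulses genuinely
  overlap in time merge into one cohort, by design.
* The cubic age–length mean is not constrained monotone; a non-monotone fit
  over the observed range raises a diagnostic rather than an error.
* The Tweedie power is profiled, not jointly estimated; differences from a
  joint REML estimate are negligible for the smooth shapes but the profiled
  AICc surface can be flat in p.
* The lunar ephemeris is geocentric; topocentric parallax (< 1°) is ignored,
  which is irrelevant at whole-date precision.
* Capture evaluation treats the fitted activity curve as truth; its
  uncertainty propagates into the Beta model only through between-year
  variation.
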