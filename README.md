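# spawntrends

Back-calculated spawning trends and seasonal-closure evaluation from
juvenile fish ageing.

## The problem

For harvested coral-reef fish, the timing of successful spawning decides
whether seasonal fishery closures protect anything at all. Direct spawning
observation is rarely feasible, and gonad histology only hints at when
spawning *could* occur. Juveniles that have already recruited carry a
better record: daily growth increments in their sagittal otoliths. Counting
increments from the settlement mark to the otolith edge gives a
post-settlement age; increments from the primordium to the settlement mark
give the pelagic larval duration (PLD). Subtracting both from the
collection date recovers each fish's hatch date — a demographically
weighted history of the spawning that actually produced recruits.

`spawntrends` implements the full inference chain for collections of
juvenile fish (≤ 250 mm), for fisheries scientists evaluating
lunar-anchored closure policies:

1. **Ageing QC** — three replicate increment counts per fish, accepted when
   every count is within 10% of the median (inclusive); age = mean of the
   three counts.
2. **PLD & back-calculation** — `hatch = collection − round(age) −
   round(mean PLD)`, with the PLD estimated from pre-settlement counts
   (study-scale calibration 27.9 ± 1.6 d).
3. **Age–length model** — recruitment cohorts from a 30-day gap rule, then
   `age ~ poly(TL, 3) + (1 | cohort)` with a log-linear dispersion model in
   length and cohort (Gaussian, `glmmTMB`), used to impute ages of non-aged
   fish (about 57% of a collection).
4. **Spawning trends** — hatch dates tallied into 73 five-day bins per
   austral year (July–June) and smoothed with a penalized-spline Tweedie
   GAM, `count = exp(β₀ + s(t))`, ε ~ Tw_p(μ, σ²), p ∈ (1, 2) profiled,
   basis dimension by lowest AICc; spawning peaks from the sign change of
   the first derivative of the fitted curve.
5. **Environmental screening** — lunar illumination (+10 h AEST shift,
   analytic ephemeris), 8-day SST composites and rainfall on the same bins;
   `count = exp(β₀ + te(SST, month) + s(year))` with AICc covariate
   screening and concurvity flags.
6. **Closure evaluation** — 5- or 9-day windows centred on the Oct–Dec new
   moons; capture proportion = fraction of predicted spawning activity on
   closed days vs the uniform expectation `closed_days/92`; Beta mixed
   regression of capture on closure duration and count with Tukey
   contrasts.

A synthetic-data generator (`simulate_collection()` and friends) emulates
the statistical structure of the field data — multi-cohort spawning pulses,
monotone juvenile growth over 23–248 mm, replicate ageing error, a 43% aged
fraction, sinusoidal SST — so the whole chain is testable without any
external data.

## Worked example

```r
library(spawntrends)

report <- run_pipeline(default_config(seed = 2))
report
#> <run_report>
#>   collected 1763 fish; 14 QC-rejected; PLD 28.1 +/- 1.9 d (n=87)
#>   aged 756 + imputed 1007 = analyzed 1763
#>   6 cohort(s); 3 austral year(s) fitted, 0 excluded
#>   closure capture 9:5 duration ratio 1.67
```

Reading this: of 1763 simulated juveniles, 756 passed replicate-count QC
and were aged directly (14 fish failed the 10%-of-median rule); the
age–length model imputed ages for the other 1007, so every collected fish
enters the analysis (the accounting identity `aged + imputed = analyzed`).
The estimated PLD from 87 otolith-core reads is 28.1 ± 1.9 days. Six
recruitment cohorts were found across three austral years, each year's
5-day-binned hatch dates were smoothed, and across the closure-policy grid
a 9-day closure captured 1.67× the spawning activity of a 5-day closure —
close to, and statistically indistinguishable from, the 9/5 = 1.8 expected
from duration alone when spawning has no lunar synchrony.

Individual stages are exported, e.g.:

```r
qc_counts(c(99, 100, 101))$mean_age        # 100
new_moons(as.Date("2021-10-01"), as.Date("2021-12-31"))
#> "2021-10-06" "2021-11-05" "2021-12-04"

y <- bin_hatch_dates(report$fish$hatch_date, 2019)
fit <- fit_spawning_smooth(y)
detect_peaks(fit, seed = 1)                # dated peaks with 95% CIs
```

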