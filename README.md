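# actipred

Forecasting cognitive decline in older adults from free-living
accelerometry.

Screening tools that flag cognitively intact older adults at risk of
near-term decline can trigger closer monitoring and earlier intervention.
`actipred` implements a complete, device-agnostic pipeline from wearable
accelerometer exports to that forecast: it reduces raw recordings to
minute-level activity signals, summarizes each subject by 98 statistical
and circadian-harmonic measures, and trains tiered gradient-boosted
classifiers for the binary outcome *any decline* in the Montreal
Cognitive Assessment (MoCA) between baseline and follow-up,

&Delta; = MoCA<sub>follow-up</sub> &minus; MoCA<sub>baseline</sub>,&emsp;declined &hArr; &Delta; < 0.

Two wear protocols are supported end to end:

| profile | raw form | rate | wear | samples/day N | window H |
|---|---|---|---|---|---|
| hip | tri-axial (x, y, z) | 30 Hz | 7 days | 2,592,000 | 1800 |
| wrist | magnitude counts | 15-s epochs | 72 h | 5760 | 4 |

## The signal and feature model

Tri-axial samples become magnitudes r(t) = &radic;(x&sup2; + y&sup2; +
z&sup2;); per-subject wear days are aligned by time of day and averaged
into one representative day r&#772;(t). Non-overlapping one-minute
windows of H samples then give three minute-level series (1440 values):

- **ENMO**(t) = (1/H) &Sigma;<sub>h</sub> max[r&#772;(t+h) &minus; 1, 0] — the
  Euclidean norm minus one, removing the static gravity component;
- **CPM**(t) = H &middot; ENMO(t) — counts per minute;
- **VMC**(t) = (1/H) &Sigma;<sub>h</sub> |r&#772;(t+h) &minus; ref| — the
  mean amplitude deviation of the window (window-mean reference by
  default).

From ENMO and VMC the package computes 48 features each — 12
distributional statistics (mean, median, SD, min, max, quartiles,
skewness, excess kurtosis, histogram entropy, beta shape &alpha;, &beta;)
and 36 harmonic measures (top-15 FFT amplitudes and their frequencies in
cycles/day, spectral entropy, power-weighted frequency moments, RMS
amplitude) — plus two cohort-quartile activity categories **C4** (from
each subject's CPM 75th percentile) and **V4** (VMC 75th percentile):
**98 accelerometry measures** per subject.

Three nested XGBoost tiers are compared on a shared hold-out split (10%
of subjects on the hip profile, 15% on the wrist profile), tuned by
stratified 5-fold cross-validation maximizing AUC:

| tier | design columns (hip / wrist) |
|---|---|
| `base` — covariates only | 7 / 6 |
| `activity` — + C4, V4 | 9 / 8 |
| `full` — + 96 signal features | 105 / 104 |

A synthetic-cohort generator (`simulate_cohort()`) emulates both device
protocols — circadian harmonic activity, per-class effect sizes on age
and baseline MoCA, outcome ratios, non-wear gaps — so the whole pipeline
runs and is tested without access to restricted cohort data.

## Worked example

```r
library(actipred)

prof   <- device_profile("wrist")
cohort <- simulate_cohort(sim_config("wrist", n_subjects = 120, seed = 42))
dat    <- process_cohort(cohort, prof)   # 120 x 109 model-ready tibble
report <- run_tiers(dat, prof, seed = 42, grid = quick_grid())
report
#> <cd_tier_report> seed 42, hold-out n = 18
#> # A tibble: 3 × 6
#>   tier     n_features n_holdout accuracy   auc auc_sd
#>   <chr>         <int>     <int>    <dbl> <dbl>  <dbl>
#> 1 base              6        18    0.444 0.358 0.0504
#> 2 activity          8        18    0.667 0.778 0.0869
#> 3 full            104        18    0.944 0.944 0.0224
```

The three rows are the nested tiers evaluated on the same 18-subject
hold-out: covariates alone carry no skill on this synthetic cohort
(AUC ≈ 0.36, chance-level at this hold-out size), adding the two
activity categories lifts AUC to 0.78, and the full 98-measure bank
reaches 0.94 — the planted circadian difference between decliners and
non-decliners is recovered from the accelerometry, not from the
demographics. `auc_sd` is the spread of AUC across the 5 CV folds.
`autoplot(report)`, `autoplot(report$reports$full, "roc")`,
`"importance"` and `"confusion"` draw the standard report panels;
`tidy()` and `glance()` return them as tibbles.

A thin command-line front end over the same functions lives in
`inst/scripts/actipred.R` (`simulate`, `process`, `run` subcommands).

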