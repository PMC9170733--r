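---
title: "From raw accelerometry to cognitive-decline forecasts: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw accelerometry to cognitive-decline forecasts: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

actipred forecasts whether an older adult's cognition will decline between
a baseline and a follow-up Montreal Cognitive Assessment (MoCA), using
nothing more invasive than a week (or 72 h) of free-living accelerometry
plus routine demographic and clinical covariates. This vignette documents
the signal model, the feature bank, the classifier protocol, the synthetic
cohort generator, and every place where the design was genuinely open and
a choice had to be made.

## The two device profiles

All processing is parameterized by a `device_profile()`:

* **hip**: a tri-axial accelerometer worn continuously for 7 days,
  sampling at 30 Hz. One day holds N = 24 x 60 x 60 x 30 = 2,592,000
  samples; a one-minute window holds H = 1800 samples.
* **wrist**: a count-based wrist device worn for 72 h. The vendor firmware
  reduces 32 Hz raw data to one magnitude per 15-s epoch, so
  N = 24 x 60 x 4 = 5760 epochs/day and H = 4 epochs/minute.

Both profiles tile a day into exactly 1440 one-minute windows. Scaled
profiles (e.g. `device_profile("hip", sampling_rate = 1)`) keep every
downstream contract — 1440 minutes, minute-aligned windows, identical
feature counts — while making simulation studies cheap; they exist for
testing and simulation, not to model any real device.

## Wear days and the valid-day rule

Days are cut at local midnight. A day is *valid* when it contains at
least 10 hours of daytime recording; subjects keeping at least one valid
day are eligible. Two choices here were open:

* **The daytime window is 06:00–22:00, configurable.** The validity rule
  presumes a notion of daytime that the protocol itself does not pin
  down; a 16-h window is common actigraphy practice and makes the 10-h
  criterion attainable without counting overnight wear.
* **Partial first/last days are kept if they pass the rule.** Validity is
  judged on daytime hours only, so a partial day with 10+ daytime hours
  carries as much usable signal as a full one.

Hip devices are treated as continuously worn (no non-wear detection);
wrist epochs carry an explicit wear flag from the device's galvanic skin
sensor, and flagged epochs are dropped before any computation. No
algorithmic non-wear detection is implemented.

## From samples to minute signals

Tri-axial samples are collapsed to the Euclidean norm
r(t) = sqrt(x² + y² + z²); a resting device reads r = 1 (gravity). The
per-day streams of each subject are aligned on the time-of-day grid and
averaged across wear days into a single representative day r̄(t)
(columnwise mean; missing slots are averaged over the days actually
present). Only valid days enter this average — averaging invalid
fragments would let a 2-h day distort the circadian profile.

Non-overlapping one-minute windows of H samples then yield three minute
series (length 1440):

* ENMO(t) = (1/H) Σ max[r̄ − 1, 0] — gravity-removed activity level;
* CPM(t) = H · ENMO(t) — the same information on a counts-per-minute
  scale (the identity is exact by construction, and tested to machine
  precision);
* VMC(t) = (1/H) Σ |r̄ − ref| — within-minute variability (mean
  amplitude deviation).

Two choices worth recording:

* **VMC reference.** The statistic is a *mean amplitude deviation*, whose
  standard reference point is the window mean, and that is the default.
  A literal variant that subtracts the window's first sample instead is
  available via `vmc_reference = "first_sample"`, because that form also
  circulates in the actigraphy literature and exact reproducibility of
  either convention matters more than arguing about it.
* **The "− 1" on wrist counts.** ENMO's gravity subtraction is applied
  identically on both profiles so that one pipeline serves both devices.
  Wrist counts are not gravity-calibrated, so there the subtraction is a
  fixed baseline shift, not a physical gravity removal. This is a
  documented caveat, not a bug.

Minutes missing more than half their samples (wrist non-wear) are emitted
as missing; present-sample averages are used otherwise. Missing minutes
are excluded from the distributional statistics and linearly interpolated
before the Fourier transform (a spectral estimate needs a complete,
evenly spaced grid; at the sub-percent non-wear rates the wrist protocol
produces, the interpolation choice is numerically irrelevant).

## The 98-measure feature bank

Each of ENMO(t) and VMC(t) contributes 48 features:

* 12 distributional statistics: mean, median, SD, min, max, 25th/75th
  percentiles, skewness, excess kurtosis, histogram entropy, and a
  method-of-moments beta shape pair (α, β);
* 36 harmonic features: amplitudes and frequencies (cycles/day) of the
  15 largest FFT coefficients, spectral entropy, power-weighted mean and
  SD of frequency, RMS amplitude, and power-weighted excess kurtosis and
  skewness of frequency.

Adding the two cohort-level ordinal categories C4 and V4 (quartile bins
of each subject's CPM and VMC 75th percentiles) gives 96 + 2 = 98
accelerometry measures per subject.

Estimator choices, all open in principle:

* **Entropy** is the Shannon entropy of the histogram bin proportions
  under the Freedman–Diaconis rule: it is maximal (log k over k occupied
  bins) for a uniform spread of activity and drops as activity
  concentrates, which is exactly the contrast the feature is meant to
  capture. It is a distributional entropy, not an entropy rate of the
  time series.
* **Beta shape** is fitted by the method of moments after min–max
  rescaling to (0, 1) with 1e-6 clipping — closed form, no iterative
  failure modes; degenerate series yield missing shape parameters rather
  than fabricated ones.
* **FFT conventions.** The 1440-point series is mean-removed, the DC
  term excluded, and the 720 positive-frequency bins retained; a day-long
  grid makes bin k exactly k cycles/day. Amplitudes are reported as
  2|F_k|/n so that a sinusoid of amplitude a reports amplitude a.
  Amplitude ties in the top-15 selection break toward the lower
  frequency, making the ordering deterministic.
* **Quartile binning** uses linear-interpolation percentiles; values on
  a cut-point fall to the lower bin. Cut-points are persisted so held-out
  subjects are binned with training-cohort cut-points.
* Skewness and kurtosis are the standardized third moment and *excess*
  kurtosis (zero for a normal distribution), in both the statistical and
  the spectral variants.

## Covariates and the outcome

The decline outcome is Δ = MoCA(follow-up) − MoCA(baseline), declined
iff Δ < 0; Δ = 0 counts as non-declined. No education point is added to
MoCA scores, since education is itself a covariate.

Covariates are ordinal-coded, one numeric column each: 7 on the hip
profile (age, gender, race, education, income, Charlson index, baseline
MoCA) and 6 on the wrist profile (no income; different race and education
dictionaries). One-hot encoding was rejected deliberately: the tier
accounting (7/9/105 and 6/8/104 design columns) only works with one
column per covariate, and gradient-boosted trees split ordinal codes
natively.

## Classifier protocol

Three nested XGBoost tiers run on one shared split: `base` (covariates),
`activity` (+ C4, V4), `full` (+ 96 signal features). The hold-out is
10% (hip) or 15% (wrist) of subjects, `floor(frac * n)` in size,
allocated across outcome classes by largest-remainder rounding so neither
class can vanish from the hold-out; everything else is training data.
Hyperparameters are tuned by stratified 5-fold CV maximizing mean fold
AUC over a 54-point grid (depth 2–4, learning rate 0.05/0.1/0.3, 50–200
rounds, subsampling 0.8/1) — small enough to be honest at n of a few
hundred. Reported per tier: hold-out accuracy at the 0.5 threshold, the
confusion matrix, hold-out AUC with the *CV-fold AUC standard deviation*
as its spread (a bootstrap hold-out SD would conflate split noise with
fold noise at these sample sizes), and total-gain importances with
zero-importance features excluded.

Leakage policy: C4/V4 cut-points are refitted on training subjects only
and applied to the hold-out (default). Cohort-wide binning — which a
single-cohort retrospective analysis would naturally use — is available
via `refit_cuts = FALSE` for literal replication; at these cohort sizes
the two differ by at most one bin for a handful of boundary subjects.

Every split, fold assignment and fit is a deterministic function of the
supplied seed, and the split manifest (hold-out ids, fraction, seed)
travels with every report.

## The synthetic cohort generator

`simulate_cohort()` exists so that every stage — CSV dialects, valid-day
filtering, signal math, feature counts, tier ordering — is exercisable
without access to restricted cohort data. Defaults encode the study
conditions the pipeline targets:

* hip-like: n = 115, 67 stable : 48 declined, 1-year MoCA change in
  [−8, 6] (integer), age 73.2 ± 5.9 with a between-class Cohen's D of
  0.457, baseline MoCA 25.4 ± 2.6 with D = 0.572, 7 continuous wear
  days;
* wrist-like: n = 575, 279 : 296, 5-year change in [−14.9, 14.9]
  (continuous, survey-estimated follow-up scores), age 67.0 ± 7.9 with
  D = 0.284, MoCA 23.4 ± 4.0 with D = 0.418, 72-h wear, 0.17% of epochs
  non-wear.

Declined subjects are simulated older and with higher baseline MoCA
(regression to the mean); gender, race, education, income and Charlson
draws follow the corresponding cohort compositions without class effects.
Follow-up scores are generated so the sign of Δ equals the true class for
every subject — the labeler must reproduce the generator's classes
exactly, and a test holds the package to that.

Activity is a rectified sum of circadian harmonics at 1, 2 and 4
cycles/day (weights 1 / 0.4 / 0.2, peak near 14:00, subject-level
log-normal amplitude variation of ~25%, minute noise scaled to the
subject amplitude). Declined subjects carry a circadian amplitude reduced
by the factor exp(−0.35 · s) and harmonic content tilted toward the
fundamental by exp(−0.25 · s), where s is `accel_signal_strength`
(default 1; 0 removes the accelerometry signal entirely). On tri-axial
profiles the minute intensity rides on a randomly oriented unit vector
added to gravity, preserving the magnitude semantics (a resting device
reads exactly 1) without pretending to biomechanics. Wrist counts carry
epoch-level noise so within-minute variability — the quantity VMC
measures — is nonzero whenever minute noise is.

What the generator does *not* emulate, hence what green tests do not
certify about real data: gait microstructure and posture transitions,
sleep architecture, day-of-week structure, device calibration error, and
long non-wear bouts. The generator validates the machinery and its
statistical calibration, not clinical effect sizes.

## Problem sizes used in the checks

The test suite runs everything at desk scale, chosen once: unit fixtures
use scaled hip profiles (1 Hz or 1/6 Hz; feature counts and window
algebra are invariant to the within-minute rate), cohort-level checks use
16-subject cohorts, the null-calibration study uses 20 cohorts of 200
wrist-profile subjects with `accel_signal_strength = 0` and zero
covariate effects (mean hold-out AUC must sit in [0.45, 0.55]), and the
skill-ordering study uses 10 cohorts of 120 subjects at default signal
strength (mean hold-out AUC of `full` must exceed `base`). The
multi-cohort studies use the compact `quick_grid()`; tuning breadth is
irrelevant to a calibration or ordering property, and the full grid is
exercised separately.

## Known limitations

* Performance numbers on synthetic cohorts say nothing quantitative
  about real cohorts; only structural and calibration properties
  transfer.
* The wrist "− 1" baseline shift makes wrist ENMO a relative, not
  physical, quantity.
* Charlson scores are taken as given integers; scoring from raw
  comorbidity questionnaires is out of scope.
* No device calibration, no imputation of long gaps, no sleep scoring,
  no activity-bout or MVPA cut-point analysis.
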