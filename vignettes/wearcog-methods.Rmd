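---
title: "Methods: from wrist-wearable signals to cognitive score prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from wrist-wearable signals to cognitive score prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Neuropsychological test batteries measure cognitive function in people with
mild cognitive impairment (MCI) well, but they cannot be administered weekly.
Wrist-wearable devices record physiological signals continuously and
passively: blood volume pulse (BVP, 64 Hz), electrodermal activity (EDA,
4 Hz), skin temperature (4 Hz), plus device-derived heart rate (HR) and
inter-beat intervals (IBI). `wearcog` implements a complete, testable
pipeline that turns such recordings into interval-level physiological
features and evaluates how well they predict neuropsychological composite
z-scores (executive function, processing speed, immediate and delayed
memory, global cognition) at two levels: absolute scores across people, and
intra-individual change.

Because real trial data of this kind are not publicly distributable, the
package ships a synthetic-cohort generator with *known* signal-cognition
coupling. Every stage of the pipeline can therefore be checked against a
recoverable ground truth, which is how the test suite works.

## Signal processing and quality control

Recordings are cut into fixed 5-minute segments aligned to a midnight-anchored
grid (288 per day) -- five minutes being the shortest recommended duration
for heart-rate-variability (HRV) measurement. Samples snap to the
nominal-rate grid by nearest timestamp (duplicates averaged); interior gaps
shorter than 30 s are linearly interpolated. Coverage is assessed **before**
interpolation, so gap repair can never manufacture a valid segment. Validity
thresholds are inclusive: at least 50% coverage for HR and temperature, 70%
for EDA and BVP, and the IBI beat count must agree with `mean(HR) * 5 min`
within 10%. Segments without valid IBI are discarded entirely -- IBI
availability is the most sensitive marker of proper device wear.

Only segments inside the calmest 5-hour night window are analyzed.
`select_night_window()` chooses the contiguous 5-h window minimizing pooled
population mean HR over a 21:00-09:00 candidate span (ties to the earliest
start); with a planted nocturnal HR minimum it reproduces the canonical
01:00-06:00 window. The pipeline config can pin the window instead: the
CI-scale demonstration does so, because it generates wear only around the
night window, where data-driven selection is ill-posed (any 5-h candidate
containing all the data ties).

Days contribute only if they hold at least four valid 5-min samples; daily
feature medians are averaged over consecutive 10-day intervals anchored at
each subject's first observed night, giving up to seven interval rows per
subject over a 70-day observation.

## The feature catalogue

A frozen registry (`feature_registry()`, 130 features) defines every output
column and the deterministic order used by pruning:

* **HRV, computed twice** -- from the device IBI stream (`IBI_*`) and from
  beats detected in raw BVP (`PPG_*`):
  * time domain: MeanNN, SDNN (sample SD), RMSSD, SDSD, CVNN, CVSD,
    MedianNN, MADNN (1.4826 scaling), MCVNN, IQRNN, pNN50/pNN20 (strict
    thresholds), min/max/range, HTI (1/128 s histogram bins);
  * frequency domain: cubic-spline resampling of the tachogram to 4 Hz,
    linear detrend, Welch PSD (120-s Hann segments, 50% overlap), trapezoid
    band powers over LF 0.04-0.15, HF 0.15-0.40, VHF 0.40-0.50 Hz, plus
    LF/HF, normalized and log variants;
  * nonlinear: Poincare SD1/SD2 defined via population variances so that
    SD1^2 + SD2^2 = 2 Var(NN) is an exact identity (SD2^2 floored at zero);
    CSI, CVI, modified CSI from the 4*SD ellipse axes; Guzik and Porta
    asymmetry indices with the directional decomposition (SD1d/SD1a,
    SD2d/SD2a, SDNNd/SDNNa and their shares); fragmentation indices PIP,
    IALS, PSS, PAS over the sign sequence of successive differences.
* **Beat detection** (`elgendi_peaks()`): two-moving-average detection on
  the squared, clipped, band-passed (0.5-8 Hz, order-2 Butterworth,
  zero-phase) pulse signal; peak/beat windows 111/667 ms, threshold offset
  beta = 0.02 of the mean squared signal. On synthetic pulse trains it
  recovers over 99% of planted beats within +/-50 ms.
* **EDA** (`eda_process()`): order-4 low-pass at 1 Hz to denoise, order-2
  low-pass at 0.05 Hz for the tonic level, phasic = difference. Skin
  conductance responses are phasic local maxima rising at least 0.01 uS
  above the preceding trough within 5 s -- the rise-time bound is the
  physiological one and rejects the slow residual bumps a zero-phase tonic
  filter leaves around large responses. Sympathetic activation is indexed
  by phasic Welch power in 0.045-0.25 Hz, optionally normalized by total
  0-0.5 Hz power.
* **HR and temperature**: mean, median, SD, min, max, least-squares slope
  per hour; the HR channel additionally passes through the same spectral
  machinery (`HR_LF`, `HR_HF`, ...), covering frequency features of the
  continuous rate signal.

All filters are wrapped in `smooth_filter()`, which mean-centers and
odd-reflection-pads before `signal::filtfilt`; without padding the
zero-initial-condition implementation leaves large edge transients on slow
filters (a constant 2 uS input deviated by up to 1.8 uS in a direct call).

Redundant features (squared Pearson correlation >= 0.95 on the interval
matrix) are pruned greedily in registry order, zero-variance columns first.
Greedy keep-first pruning is deterministic; the kept count is an emergent,
data-dependent quantity, not a contract.

## Outcomes: imputation and centering

Composite z-scores exist only at baseline and post-intervention. Interval
values are interpolated with a normalized Gompertz sigmoid

g(u) = (exp(-b e^{-cu}) - e^{-b}) / (exp(-b e^{-c}) - e^{-b}),

so the series passes *exactly* through both assessments; `(b, c)` are pure
shape parameters, default `b = 3, c = 4` (a mid-course value of
g(0.5) ~ 0.6875, i.e. most improvement front-loaded, plateauing late --
the standard assumption for short-term cognitive change). Linear and
seeded-uniform random interpolation serve as comparators;
`imputation_concordance()` compares feature-outcome correlation vectors
between datasets (Pearson r plus paired t-test), and random imputation
demonstrably attenuates planted correlations relative to Gompertz.

Two dataset variants are analyzed: *uncentered* (absolute scores), and
*centered*, where features are reduced by each subject's median and
outcomes by the half-range (y0 + y1)/2 -- isolating intra-individual change.

## Association screening and prediction

Pearson and Spearman correlations are computed for every outcome-feature
pair (two-sided p via the t transform; pairwise-complete, n >= 3), adjusted
by Benjamini-Hochberg FDR across all pairs separately per statistic family,
with significance requiring **both** adjusted p-values < 0.05 strictly.
A random-intercept mixed model (`lme4`, REML; slope p by normal
approximation; fixed-effect R^2 = Var(bx)/(Var(bx) + Var(intercept) +
Var(residual))) screens the same pairs at the intra-individual level.

Prediction uses three learners -- elastic net (`glmnet`, alpha 0.5, fixed
lambda 0.05, training-fold standardization), random forest (500 trees) and
gradient boosting (`xgboost`, 300 rounds, depth 3, eta 0.1) -- crossed with
four selection thresholds (0.05, 0.001, 1e-4, 1e-5) and three feature sets
(demographics = age + sex with female coded 1, combined, physiology-only).
Hyperparameters are fixed, documented defaults; searching them is a
non-goal. Feature selection (both-p rule, then greedy |r| > 0.9
multicollinearity pruning ordered by descending |Pearson r|) runs **inside
every training fold**; an audit trail records the exact row indices touched,
and `detect_leakage()` fails on any overlap -- the test suite proves that
injected leakage is caught. Cross-validation is leave-one-subject-out
(generalization to new people) and leave-one-interval-out (new periods of
known people); metrics (Pearson r, Spearman rho, MAE) are computed on the
pooled out-of-fold predictions, with gains reported against the matched
demographics-only baseline. The best model per outcome and scheme is the
highest Pearson r, ties to fewer features then to the elastic net.

## The synthetic cohort

`simulation_config()` defaults describe the emulated study conditions: 17
analyzable subjects, 70 observation days (7 intervals), night wear inside
01:00-06:00 with 15% whole-night non-wear, baseline composites ~ N(0, 1)
with change ~ N(0.2, 0.4), latent Gompertz trajectories with interior noise
SD 0.05. RR series use direct interval modulation -- mean 850 ms plus
sinusoids at 0.10 Hz (LF, 25 ms) and 0.25 Hz (HF, 20 ms) plus white jitter
(20 ms) -- chosen over integral-pulse-frequency modulation because every
downstream feature then has a closed-form oracle. BVP renders one
gamma-shaped pulse template per beat (peak aligned to the beat time); EDA is
a tonic ramp plus Poisson-timed Bateman responses (tau1 = 4 s,
tau2 = 0.75 s); temperature is a slow sinusoid plus noise; the HR channel is
the instantaneous rate resampled at 1 Hz, so the IBI-vs-HR consistency check
holds by construction. Coupling is linear: a chosen physiological parameter
(by default the HF amplitude) equals its base value plus slope x the
subject's latent executive-function score for that interval, floored at
physiological minima. Hierarchical seeds (master -> subject -> night ->
channel) make cohorts exactly reproducible.

What the generator does *not* emulate: motion artifacts, respiration,
device-specific beat-detection dropouts, non-stationary noise, daytime data,
or realistic missing-data mechanisms (non-wear is whole-night Bernoulli).
Passing tests therefore demonstrate correctness of the pipeline's
*mechanics* and recoverability of planted effects, not clinical performance
on real wearables.

Between-subject physiological heterogeneity beyond the cognition-coupled
variation defaults to zero. This keeps the zero-coupling cohort exchangeable
so its null behavior is interpretable; it is also the main reason the
synthetic recovery correlations are higher than anything a real cohort
would show.

## Problem sizes, numerical choices, known limitations

* The demonstration (`run_demo()`) and the acceptance script run the full
  17 x 70-day cohort with ~25 minutes of nightly wear (five 5-min
  segments), and the multi-seed recovery/null replicates omit the BVP
  channel (the detector has separate truth-matched checks; the IBI stream
  carries the coupled feature). These sizes keep a complete multi-seed run
  on one CPU in minutes while preserving the study's subject/interval
  structure.
* Welch segments shorter than 120 s fall back to a single full-length
  window; tachogram spectra require a 30-s span; difference-based HRV
  statistics require >= 2 (time), >= 4 (nonlinear) intervals; degenerate
  Poincare axes (SD1 or SD2 = 0) mark ratio features missing rather than
  dividing by zero.
* NN cleaning keeps intervals strictly inside (200, 3000) ms and re-derives
  beat times from the retained intervals.
* With direct interval modulation, HF-amplitude coupling propagates into
  *every* beat-derived feature (SDNN, RMSSD, SD1, band powers, ...), so the
  coupled feature's rank among all features is exchangeable within that
  proxy family; the discriminative claim that holds -- and is tested -- is
  that it dominates the features of uncoupled channels.
* Under zero coupling, LOSO-pooled correlations of selected-feature models
  have heavy tails: outcomes are nearly constant within subject, so
  row-level selection p-values are effectively computed on ~17 independent
  units, and the maximum spurious subject-level correlation over ~50
  candidate features can reach |r| ~ 0.5 in a given cohort draw. This is a
  property of the screening design at this sample size, not of the
  implementation (the leakage audit is clean), and it is the reason the
  null-cohort checks are phrased as medians over seeds.
* The Gompertz shape parameters are a declared package default, not a
  reconstruction of any fitted values; endpoint-exactness is the property
  the design requires, and all downstream results are invariant to
  re-deriving the interior shape within the monotone family.
* Whether imputed interior scores align to wearable intervals by calendar
  date or by index is resolved *by index*; with interval anchoring at each
  subject's first observed night the two coincide for fully observed
  subjects.
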