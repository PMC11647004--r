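---
title: "Methods: dose-volume and dosiomics survival modelling with dosurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-volume and dosiomics survival modelling with dosurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Survivors of childhood cancer treated with radiotherapy carry a lifelong
excess risk of severe cardiac disease. Cohorts that follow such survivors
have two defining statistical features: follow-up spans decades, and the
event of interest is rare — roughly 5% of subjects experience a high-grade
cardiac event while about 95% are right-censored. The scientific question
`dosurv` addresses is whether *texture-style* summaries of the 3D radiation
dose delivered to the heart ("dosiomics") predict late cardiac disease
better than the classical summaries (mean heart dose, dose-volume
histogram indicators), once both are embedded in survival models that
respect the heavy censoring.

The package implements the full analysis pipeline as reusable, tested
components, and ships a seeded synthetic-cohort generator so that every
stage can be exercised end to end without access to patient data.

## Dose preprocessing

A patient's radiotherapy course may comprise several sessions, each a 3D
dose grid (Gy, 2 mm isotropic voxels) with binary masks for the whole
heart and five subparts (left/right atrium, left/right ventricle,
myocardium). `aggregate_sessions()` sums the voxelwise dose of all
sessions starting within six months (183 days, boundary inclusive) of the
first; later sessions are ignored. Masks are taken from the first session:
the anatomy is a single reconstructed surrogate per patient, so it does
not change between sessions.

`clip_outliers()` then thresholds reconstruction artifacts at D2, the 98%
quantile of the in-mask dose: all whole-heart voxels above the threshold
are set to it. Two details are deliberate:

* The quantile is computed over the *whole-heart* mask once per patient
  (the enclosing region), before any per-subpart extraction, so subpart
  features see a consistently clipped field.
* The threshold uses the inverse-CDF (order-statistic) quantile estimator
  rather than an interpolating one. With interpolation, the 98% quantile
  of the clipped distribution is strictly smaller than the original
  threshold whenever the quantile falls between order statistics, so
  clipping twice would keep shaving dose off. With the order-statistic
  estimator the threshold is itself a data value and clipping is exactly
  idempotent. The dose-volume indicators below are *not* clipped-related
  and keep the conventional linear-interpolation quantiles.

## Feature extraction

Four nested feature groups are extracted per region (whole heart, or each
of the five subparts):

* **Mean dose** (1 value).
* **Dose-volume indicators** (24): $D_x$, the minimum dose received by the
  hottest $x\%$ of the region for
  $x \in \{2,5,10,20,30,40,50,60,70,80,90,98\}$ (so $D_{70}$ is the 30%
  dose quantile), and $V_d$, the percentage of the region receiving at
  least $d$ Gy for $d \in \{1,2,5,10,15,20,25,30,35,40,45,50\}$. The grid
  contains every indicator commonly reported for cardiac dosimetry
  ($D_2$, $D_{70}$, $V_2$, ...) and totals exactly 24.
* **First-order statistics** (18): energy, total energy (voxel volume in
  mm^3 times energy), entropy, minimum, 10th/90th percentiles, maximum,
  mean, median, interquartile range, range, mean absolute deviation,
  robust MAD (within the 10th-90th percentile band), RMS, skewness,
  kurtosis (not excess), variance (population), uniformity.
* **Full dosiomics** (93): the 18 first-order features plus 75 texture
  features from five gray-level matrix families — GLCM (24), GLRLM (16),
  GLSZM (16), NGTDM (5), GLDM (14).

Texture features are computed on a discretized volume: doses are binned at
a fixed width of 0.5 Gy with the bin origin at the in-mask minimum,
`level = floor((dose - min) / 0.5) + 1`. Tying the origin to the minimum
makes every level-based feature invariant to adding a constant dose. The
level count is `floor((max - min)/0.5) + 1`, so a maximum dose lying
exactly on a bin edge occupies its own top level, consistent with the
level formula.

All matrix families use distance 1 and 26-connectivity: the 13 unique 3D
direction vectors for GLCM and GLRLM (features computed per direction and
averaged; directions without any in-mask pair are dropped from the
average), 26-connected zones for GLSZM, the 26-neighbourhood for NGTDM
(voxels with no in-mask neighbour do not contribute) and GLDM (dependence
= 1 + number of neighbours with identical level). Matrix construction is
in C++; features are computed in R from the matrices.

Degenerate single-level regions — common here, because non-irradiated
hearts receive exactly zero dose — are given finite conventional values:
entropy 0, uniformity 1, GLCM correlation and MCC 1, information measures
0, skewness/kurtosis 0. These conventions are exercised constantly by the
synthetic cohort's ~45% zero-dose patients.

Every feature column is named `region__family__feature`, so a flat tibble
retains full provenance (`feature_metadata()` parses it back).

## Predictor screening

Screening is always refit on the training part of each resampling split
(`screen_predictors()` returns a frozen result that `apply_screening()`
merely projects onto new data, so no statistic ever sees test outcomes):

1. **Degenerate removal**: constant columns, and the later of any pair
   with sample correlation exactly 1 (a tolerance of 1e-12 absorbs
   floating-point noise).
2. **Diagnosis-group indicators**: each of the 42 first-cancer indicator
   variables is tested against the event indicator with a 2x2 Pearson
   chi-squared test without continuity correction, or Fisher's exact test
   when the exposed-with-event cell holds fewer than 10 cases; indicators
   with p < 0.01 are kept. ("Fewer than ten cases" is read as the
   exposed-with-event cell, the cell whose sparsity actually invalidates
   the chi-squared approximation.)
3. **Redundancy elimination** (dosiomics groups only, and per region when
   features come from subparts): complete-linkage hierarchical clustering
   on the dissimilarity 1 - Kendall's tau-b, cut at height 0.2. Complete
   linkage guarantees every within-cluster pair has tau >= 0.8. Each
   multi-member cluster contributes one representative: the member with
   the largest hazard ratio in a multivariate Cox model on the
   standardized members (per-SD hazard ratios, otherwise column scale
   would decide). If that joint fit fails (collinearity at tau >= 0.8 is
   routine), univariate Cox fits choose the representative instead, and
   the fallback is recorded. Ties go to the earliest column name for
   determinism. Kendall's tau-b is computed in C++ with Knight's
   O(n log n) algorithm; the tau-b variant handles the heavy ties of
   discretized features.

## Survival models

All four models expose one prediction contract: a scalar risk score
(higher = riskier) and $S(t\mid X)$ on any time grid, valid and
non-increasing.

* **Cox proportional hazards** (`fit_cox()`): partial likelihood with
  Efron tie handling, Breslow baseline cumulative hazard, so
  $S(t\mid X) = \exp(-\Lambda_0(t)\,e^{\beta^\top X})$.
* **Cox Lasso** (`fit_cox_lasso()`): penalized path with 5-fold
  cross-validated partial-likelihood deviance; the penalty is the largest
  within one standard error of the minimum (the 1-SE rule), and the
  surviving features are refit unpenalized, removing the shrinkage.
  Columns are standardized inside the path; all non-intercept columns are
  penalized, clinical ones included. The path stops at
  `lambda.min.ratio = 0.05` and at `dfmax = events/2` active features:
  with ~5% events the tiny-penalty tail is numerically unstable, never
  selected, and dominates runtime.
* **Cox bootstrap Lasso** (`fit_cox_bootstrap_lasso()`): 100 bootstrap
  resamples of the training rows (resamples with fewer than two events
  are redrawn and logged). On each, a penalized path is fitted and the
  reference penalty $\lambda^*$ is its deviance-minimizing point (the
  smallest penalty of the df-bounded path). Walking from the sparsest
  penalty towards $\lambda^*$, each candidate's selected-feature
  unpenalized refit is compared to the $\lambda^*$ refit by a likelihood
  ratio test (level 0.05, df = difference in feature counts; identical
  supports accept trivially); the first non-rejected candidate's features
  are recorded. Features selected in at least 90% of bootstraps form the
  final set, refit unpenalized on the whole training data. An empty final
  set yields a valid baseline-only model, never an error, so resampling
  loops cannot abort.
* **Random survival forest** (`fit_rsf()`, via `ranger`): bootstrap
  aggregation of survival trees split by the log-rank statistic, ensemble
  Nelson-Aalen survival curves, mortality (summed cumulative hazard) as
  the risk score. Single-threaded with an explicit seed, so fits are
  bit-reproducible. Two splitting modes are exposed: exhaustive log-rank
  search over all thresholds, and the Extra-Trees variant that scores a
  handful of random thresholds per candidate feature with the same
  log-rank statistic. On wide feature tables the exhaustive search is
  orders of magnitude slower for near-identical discrimination, so the
  desk-scale profile uses the randomized variant (5 random splits, 100
  trees); the cohort-scale profile keeps the exhaustive search with 500
  trees and a tuned grid.

`tune_hyperparameters()` evaluates a grid with stratified 5-fold
cross-validation, maximizing Harrell's C; ties go to the least complex
point (fewest trees, smallest mtry, largest terminal nodes).

## Prediction-error estimation

* **Harrell's C**: concordant fraction of comparable pairs (the earlier
  subject had an event); risk ties credit 0.5.
* **IPCW C** (`ipcw_c()`): Uno-type weights
  $1/\hat G(T_i-|Z_i)\hat G(T_i-|Z_j)$, where $\hat G$ is the censoring
  distribution fitted *on training data* — a Cox model on sex, age
  category and the two chemotherapy flags (the clinical covariates
  except the first-diagnosis group), falling back to Kaplan-Meier when no
  covariates are available or the fit fails. Weights are capped at their
  own 99th percentile to guard against $\hat G \to 0$ near the end of
  follow-up. With no censoring every weight is 1 and the index equals
  Harrell's C exactly. The bounded variant $C_\tau$ discards pairs whose
  event time exceeds the horizon $\tau$.
* **Brier score** BS($\tau$): IPCW decomposition — subjects with an event
  by $\tau$ contribute $\hat S(\tau)^2/\hat G(T-)$, subjects still at
  risk contribute $(1-\hat S(\tau))^2/\hat G(\tau)$, subjects censored
  before $\tau$ contribute only through the weights.
* **IBS**: trapezoidal integral of BS($\tau$) over the 1-60-year grid
  (1-year steps), normalized by the grid span; grid points beyond the
  observed follow-up are dropped with a warning.
* **Stratified 5-fold CV** (`run_cv()`): events and censored subjects are
  partitioned separately, so fold event counts differ by at most one and
  every fold carries ~5% events. Screening, tuning, model and
  censoring-model estimation happen inside each training fold.
* **Bootstrap error curves** (`bootstrap_error_curves()`): per bootstrap
  resample, every requested pipeline is refitted on the in-bag rows
  (hyperparameters fixed at their cross-validated choice) and BS($\tau$)
  and $C_\tau$ are computed on the out-of-bag rows at every horizon;
  horizons with no usable pairs are flagged missing and excluded from the
  mean curves.
* **Model comparison** (`wilcoxon_compare()`): two-sided rank-sum test on
  fold-wise IPCW C values. For the small fold counts involved the
  p-value comes from exact enumeration of the rank-sum distribution with
  midranks, which handles ties and degenerate (all-equal) samples
  exactly; with 5 folds per arm the smallest attainable two-sided p is
  2/choose(10,5) ≈ 0.008, so these p-values are descriptive, not
  confirmatory.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not any real patient:

* **Covariates**: sex (45% female), age-at-diagnosis categories with
  probabilities (0.54, 0.20, 0.21, 0.05), exactly one of 42
  first-diagnosis groups per patient (decreasing prevalence ~1/(g+2)),
  anthracycline (35%) and alkylating-agent (55%) exposure.
* **Dose fields**: ~45% of patients are non-irradiated (zero dose,
  mirroring a cohort whose median heart dose is near zero). Irradiated
  patients receive 1-3 sessions (probabilities 0.65/0.25/0.10, gaps
  uniform on 7-200 days so the six-month rule is exercised) on a
  per-patient grid whose dimensions sit between (16, 20, 22) and
  (67, 70, 71) voxels (Beta(2,3)-scaled, putting typical sizes near the
  observed mean shapes). Each session is a sum of 1-3 axis-aligned 3D
  Gaussian "beams" plus truncated Gaussian noise — enough local dose
  heterogeneity to light up every texture family without modelling beam
  geometry. All sessions are scaled jointly so the window-aggregated
  whole-heart mean dose equals a target drawn from a log-normal
  (median 1.8 Gy, log-SD 1.2) capped at 48 Gy.
* **Outcomes**: a proportional-hazards model with Weibull baseline
  $\Lambda_0(t) = (t/\text{scale})^{2.8}$ and default log-hazard
  coefficients 0.08/Gy on mean heart dose, 0.8 and 0.4 on the two
  chemotherapy flags, 1.0 and 0.6 on two diagnosis groups. Censoring is
  uniform on 2-60 years with administrative censoring at 60 (an optional
  covariate-dependent mode exists to make IPCW estimation consequential).
  The Weibull scale is calibrated at construction by simulating the
  covariate marginals at n = 20 000 and solving for the 5% event target,
  so the realized event fraction matches the target within Monte-Carlo
  error. Because the generator scales dose fields to their sampled
  target, `generate_cohort(volumes = FALSE)` can draw the identical
  patient-table distribution without building any volume — used for
  large replicated calibration and recovery studies.

What the generator does **not** emulate: anatomically realistic hearts or
beams, correlations between dose and chemotherapy or diagnosis beyond the
hazard, competing risks, and secular trends in treatment. Passing tests
therefore demonstrate the *statistical machinery* — calibration,
selection, censoring-aware scoring — on data with the right shape, not
clinical validity on real cohorts.

## Workflow orchestration and problem sizes

`run_experiment()` executes the full grid: 16 pipeline specs (Cox on mean
heart dose; Cox, Cox Lasso and RSF on dose-volume indicators; Cox Lasso,
bootstrap Lasso and RSF on first-order and full dosiomics at both spatial
scales, with redundancy screening), stratified 5-fold cross-validation of
each, a summary table flagging the best C-indexes (maxima) and best IBS
(minimum), a rank-sum comparison of the best spec per learned-model class
against the Cox mean-heart-dose reference, and optionally bootstrap
out-of-bag error curves for the representative specs. Every random draw
derives from one master seed through named substreams, so reruns are
byte-identical.

Two profiles fix the problem sizes. The *desk* profile — 2 000 patients,
20 bootstrap resamples, 100-tree randomized-split forests — is sized so
the complete 16-spec experiment runs on a single workstation core in
minutes and is the scale at which the package's own test suite exercises
the pipeline end to end. The *cohort* profile — 7 367 patients, 100
bootstraps, exhaustive log-rank forests with a tuned grid — reproduces a
cohort-scale setup and is correspondingly compute-hungry. Tests use
smaller cohorts still (hundreds of patients) where only correctness, not
power, is at stake.

## Numerical choices and edge cases

* Ties in the Cox partial likelihood: Efron.
* Quantiles: linear interpolation (type 7) everywhere except the
  outlier-clipping threshold (type 1, see above).
* Aliased (NA) Cox coefficients in non-strict fits are dropped and the
  model refit on the estimable subset; strict fits error instead, as do
  separation and non-convergence.
* Linear predictors are capped at ±700 before exponentiation so that
  grossly overfitted models still yield defined (0/1) survival rather
  than NaN from `0 * Inf`.
* Empty feature selections are valid baseline-only models (Nelson-Aalen
  curve, risk score 0): resampling never aborts because a fold selected
  nothing.
* `stats::wilcox.test` cannot compute exact p-values with ties, so the
  fold-wise comparison enumerates the rank-sum distribution directly for
  up to 20 observations.
* The discretized array is cropped to the mask's bounding box before
  matrix construction: the cropped-away space contains no in-mask voxel
  pairs, runs, zones or neighbourhoods, so features are unchanged while
  subpart extraction avoids scanning mostly-empty grids.

## Known limitations

* The synthetic dose model is axis-aligned Gaussian; its texture spectrum
  is smoother than a clinical plan's.
* The IPCW censoring model assumes proportional hazards for censoring in
  the clinical covariates; the Kaplan-Meier fallback assumes independent
  censoring.
* Fold-wise rank-sum comparisons with 5 folds cannot reach conventional
  significance; they rank models, they do not confirm differences.
* The randomized-threshold forest trades a little split optimality for a
  large constant-factor speedup; at cohort scale the exhaustive search is
  recommended.
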