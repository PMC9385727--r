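---
title: "Inferring anxiety symptom severity from wearable movement data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring anxiety symptom severity from wearable movement data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Generalized anxiety disorder (GAD) is common, disabling, and under-detected;
its assessment relies on clinical interviews that are costly to administer at
scale. `actigad` implements a digital-phenotyping pipeline that asks how much
of a person's interview-based GAD symptom severity can be recovered from one
week of passively collected movement data: minute-epoch activity counts from
a hip-worn accelerometer, worn during waking hours only. The pipeline covers
the full path from raw count tables to evaluated risk scores — non-wear
detection, compliance filtering, time-series featurization, stacked
gradient-boosting with out-of-sample prediction, and risk-score evaluation —
and ships a synthetic cohort generator so that every stage, and the pipeline
as a whole, is testable without access to the original survey data.

# Data model

A subject's recording is an `epoch_series`: `n_days` x 1440 non-negative
integer counts at one-minute epochs. The interview record carries the 20
CIDI-style GAD items (screener and duration/frequency items, worry quality
items, and somatic items such as restlessness, irritability, fatigue, muscle
tension and sleep trouble), a composite index of major depressive disorder
(MDD) severity, and demographics (age, gender, ethnicity). The symptom
severity target is the sum of per-item z-scores across the analyzed cohort;
"elevated" means more than one standard deviation above the cohort mean.

# The synthetic cohort generator

The generator is a first-class, tested module, not a fixture. It emulates
the statistical structure the analysis assumes:

* **Latent severities.** `theta_gad` is standard normal; `theta_mdd` is
  correlated with it at a configurable level (default 0.5, reflecting the
  well-documented comorbidity of the two syndromes).
* **Movement dynamics.** Daytime minutes (900 per day; the device is off
  during a nightly window, so nights are structural zeros) follow a
  two-state rest/active Markov chain. Active minutes emit gamma counts
  (mean 350 counts/min, shape 1.5, floored at 1); rest minutes are zero with
  sojourns capped at 59 minutes so genuine wear can never produce a
  non-wear-length zero run. `theta_gad` shifts three channels, each scaled
  by `effect_size_movement` (default 0.3) per latent SD: the state-switching
  log-odds (fragmentation — the psychomotor-agitation channel), the log mean
  active intensity, and the log gamma shape (dispersion, inverted). The
  original study does not state which movement properties carried its
  signal; these channels are a modeling choice, selected because they are
  exactly what the feature catalog measures, which makes parameter recovery
  meaningful. Passing the pipeline's calibration tests therefore shows the
  artifact can find coupling of this kind — it is not a claim about the
  physiological mechanism in real cohorts.
* **Compliance.** Daily wear propensity is Beta(0.5, 1.0), drawn
  independently of severity (the study this emulates reported a near-zero
  compliance-severity correlation, r = -0.06). With probability
  `1 - compliance` per day, one long all-zero non-wear bout
  (Uniform(450, 850) minutes) is inserted. These two parameters were
  calibrated once, by simulation against two facts about the source cohort —
  roughly 44.5% of 593 recruited subjects passed the half-week wear filter,
  and excluded subjects averaged about one-third compliance — and then
  frozen.
* **Interviews.** Binary items follow a two-parameter logistic item-response
  model, `P(yes) = logistic(a_j (theta - b_j))`; ordinal items follow a
  graded-threshold model with evenly spaced thresholds (span 2.4 latent SD)
  centered on the item location, with levels mapped to the instrument's
  response options (e.g. often/sometimes/rarely/never -> 4 levels, coded
  ascending with severity; month counts -> 13 levels). A "no" on the
  screener forces all downstream items to their no-symptom level, mirroring
  interview skip logic. Item discriminations and locations are defaults
  chosen to give realistic endorsement gradients; all are configurable. The
  MDD composite is `theta_mdd` plus Gaussian noise (SD 0.6) because the
  source study never lists its MDD items.
* **Demographics** are generated with the source cohort's category
  proportions but are causally inert; they exist to exercise the
  partial-correlation machinery.

What the generator deliberately does **not** emulate: nighttime movement
(absent from the source data), survey weights, item content of the MDD
interview, and any non-movement channel (light, heart rate). Results on
synthetic cohorts therefore speak to the pipeline's correctness and
calibration, not to field performance.

# Non-wear detection and the compliance filter

A minute is non-wear when it lies in any window of at least 60 minutes whose
counts are all below 100 with at most 2 nonzero "interruption" minutes;
interruption minutes inside a qualifying window are labeled non-wear
(whole-window convention). This follows the wear-time convention published
alongside national actigraphy releases; the source study cites but does not
restate those parameters, so all three are exposed in `nonwear_params()`.
The implementation is a linear-time sweep over window start positions; a
brute-force exhaustive-window oracle in the test suite verifies exact
agreement on randomized series.

"Wore the actigraph at least half the week" is operationalized as total wear
minutes of at least `0.5 * n_days * 900` — a fraction of the expected
daytime wear window — rather than a count of valid days, because the source
reports a continuous mean compliance among non-compliant subjects. The
valid-days interpretation is selectable (`mode = "days"`). The filter is
monotone in its threshold by construction.

# The feature catalog

Day-level features are computed per valid day (at least 600 wear minutes, a
conventional actigraphy threshold) on the day's wear-only minutes and
aggregated across days by mean and SD; wear-time totals/bouts and
seasonal-decomposition strengths are computed once per week. Non-wear gaps
are closed by concatenation by default (`gap_policy = "zero_fill"` is the
alternative); gap-closing distorts long-lag features, which is why the
policy is recorded in the feature-matrix metadata sidecar. Day-level
windowing is our choice — the source does not state whether features were
computed per day, per bout, or per week — made because non-wear gaps and
nightly removal break the week into natural day units.

The families and the estimator choices that needed fixing:

* **Distributional**: mean, SD, skewness, kurtosis, RMSSD, and the
  10th/30th/70th/90th quantiles under the linear-interpolation convention
  (type 7).
* **Entropy**: spectral entropy (Shannon entropy of the normalized
  periodogram over log number of frequencies, in [0, 1]); binary entropy of
  the proportion of minutes above the series mean (the threshold is our
  choice; the source says only "binary entropy").
* **Autocorrelation**: ACF at lags 1-3, sum of squared first-10 ACF, first
  zero crossing.
* **Tiled-window variance**: stability (variance of tile means) and
  lumpiness (variance of tile variances), tile width 60 minutes.
* **Flat spots**: longest run within 10 equal-width value bins
  (right-closed bins; a constant series returns its full length).
* **Decomposition**: trend and seasonal strengths
  `max(0, 1 - Var(remainder)/Var(component + remainder))` at period 1440.
  The default decomposition is the classical moving-average one (an O(n)
  cumulative-sum implementation, numerically identical to the textbook
  filter); a loess-based variant is selectable and the choice is recorded in
  the output metadata.
* **Stationarity**: KPSS level statistic (Bartlett long-run variance, lag
  `trunc(4 (n/100)^0.25)`) and the augmented Dickey-Fuller t statistic
  (intercept, `trunc((n-1)^(1/3))` lagged differences). These are
  implemented in the package (standard econometric formulations) because no
  installed package in the target environment provides them.
* **Nonlinearity**: the Terasvirta neural-network-type statistic, chi-squared
  form on the quadratic and cubic Volterra terms of the lagged series, and
  the R-squared gain of a cubic-in-lag regression over a linear one.
* **Heterogeneity**: after removing mean, linear trend and AIC-selected
  AR(p <= 5) structure, the ARCH-LM statistic (12 lags) and the fitted
  `alpha + beta` of a Gaussian GARCH(1,1) likelihood (variance-targeted,
  Nelder-Mead on transformed parameters, with the conditional-variance
  recursion evaluated by a linear filter). GARCH non-convergence leaves
  ARCH-LM reported and `alpha + beta` missing.
* **Memory**: Hurst exponent by rescaled-range analysis over a dyadic grid
  of block sizes (log-log slope, clamped to [0, 1]). The estimator choice is
  recorded; the known small upward bias of R/S on memoryless data (about
  0.52-0.55 at these lengths) is accepted and covered by the calibration
  test band.
* **Trend**: Holt's additive level-plus-trend exponential smoothing; final
  smoothed slope and fitted smoothing parameters.
* **Spectral**: periodogram band powers for periods above 8 h, 1-8 h and
  below 1 h, summing to the series variance (Parseval).

Missingness is explicit: a feature is `NA` exactly when its preconditions
fail (constant day, insufficient length, non-convergence), never by silent
NaN propagation.

# The stacked ensemble

The target is the continuous symptom composite; elevated classification is
derived downstream from the same risk score. The architecture mirrors the
source description — 100 lower-order boosted models "each trained on
separate machine learning features" and two higher-order boosted ensembles
that are averaged — with the gaps filled as follows:

* Features are dealt round-robin, after a seeded shuffle, into
  `min(100, n_features)` disjoint subsets (the default catalog has 71
  features, so lower models are univariate); family-blocked partitioning is
  selectable.
* The two meta-models are boosted regressors differing in seed and depth
  (2 and 3); their outputs are averaged.
* Nesting: within each of 4 outer folds, inner 4-fold out-of-fold
  predictions from the lower models form the meta-training matrix — without
  this nesting the stack would leak the training targets into the meta
  tier. Lower models are then refit on the full outer-training set to score
  the held-out fold. Every subject's risk score comes only from models that
  never saw that subject's target; the test suite verifies this by flipping
  held-out targets and requiring bit-identical predictions.
* Booster defaults are conservative for cohorts of a few hundred subjects:
  lower tier depth 2, 60 rounds, learning rate 0.1; meta tier depths 2/3,
  150 rounds, learning rate 0.05; no subsampling, single-threaded, so runs
  are bit-reproducible. Missing feature values are handled natively by the
  booster's default-direction splits.
* Subject and feature orderings are canonicalized (sorted) before fold
  assignment and partitioning, so predictions are invariant to input order.

Raw scores are percentile-normalized (average ranks, so ties share a value
and the transform is monotone). Probabilities for the Brier score come from
an out-of-fold univariate logistic calibration of the raw score against the
elevated flag — the source reports a Brier score without stating its
probability source, so this choice is ours; a single-class training fold
falls back to the training prevalence.

# Evaluation

* Correlation intervals use the Fisher z transform with standard error
  `1/sqrt(n - 3)`; the atanh argument is clamped inside (-1, 1) so perfect
  correlations do not overflow. The partial correlation (risk score vs
  composite given age, gender, dummy-coded ethnicity) residualizes both
  variables by least squares and — deliberately — keeps the unadjusted
  `1/sqrt(n - 3)` standard error, because that exactly reproduces the
  printed interval of the partial correlation in the source results; the
  covariate-adjusted degrees of freedom are available via `adjust_df`.
  A variable fully explained by the covariates gets partial r = 0 rather
  than an artifact of numerical noise.
* AUC uses the rank (concordance) formulation with tie correction; a test
  verifies exact agreement with trapezoidal integration of the ROC curve.
  The "optimal cutpoint" maximizes Youden's J (the criterion is unnamed in
  the source), ties broken toward specificity.
* Odds-ratio curves dichotomize the percentile at each threshold 1..99;
  zero cells engage the Haldane-Anscombe +0.5 correction and Woolf
  intervals are computed on the corrected table. The inverse curve uses
  "no symptoms" (every item at its no-symptom level) as the outcome.
* The per-symptom profile reports Pearson (point-biserial) correlations of
  the risk score with each item; zero-variance items are flagged as
  range-restricted rather than silently dropped.

# Calibration properties and problem sizes

The acceptance suite exercises the whole artifact under the generator's
study conditions, scaled to cohorts of 200 subjects before attrition
(roughly 90 analyzed) with 10 replicate seeds per condition — sizes chosen
to keep the full suite comfortably reproducible on a single CPU; the
acceptance script's headline run uses 400 subjects, matching the
specification's calibration scenario:

* **Null coupling** (`effect_size_movement = 0`): mean |out-of-sample r|
  below 0.1, mean AUC within [0.45, 0.55], and the 95% interval covering 0
  in at least 90% of runs — type-I control of the entire pipeline.
* **Default coupling** (0.3): out-of-sample r above 0.3 and AUC above 0.7 in
  at least 90% of runs — the qualitative shape of the source's headline
  result, on the conservative side since the synthetic coupling is not tuned
  to reproduce its magnitudes.
* **Discriminant structure**: with latent GAD-MDD correlation 0.5 and
  movement coupled only to GAD severity, the risk score correlates more
  with the GAD composite than with the MDD composite in at least 90% of
  runs.

# Known limitations

* The headline statistics of the source study were computed on its real
  cohort and are not reproducible without those data; only the closed-form
  intervals recomputable from printed (r, n) pairs are asserted numerically.
* The generator's movement-severity coupling channels are a modeling device;
  real actigraphy exhibits circadian and weekly structure, autocorrelated
  compliance, and measurement idiosyncrasies the generator does not model.
* Gap-closing concatenation biases long-lag and spectral features near
  non-wear boundaries; the zero-fill alternative biases them differently.
  Both are explicit, recorded choices.
* The R/S Hurst estimator and the hand-implemented KPSS/ADF/Terasvirta
  statistics use fixed, documented lag conventions; other conventions give
  slightly different values and would need the exposed parameters changed.
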