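# actigad

Digital phenotyping of generalized anxiety disorder (GAD) symptom severity
from one week of wearable movement data.

GAD — chronic, hard-to-control worry with somatic symptoms such as
restlessness, irritability and muscle tension — is common and
under-detected, and interview-based assessment is expensive. This package
implements an end-to-end analysis that infers interview-based GAD symptom
severity from minute-epoch actigraphy counts collected during waking hours:

1. **Actigraphy I/O and wear time** — long-format epoch CSVs
   (`subject_id, day, minute, counts`), non-wear detection (≥ 60-minute
   zero-count windows allowing ≤ 2 interruption minutes under 100 counts),
   and the half-week compliance filter.
2. **Time-series features** — a catalog of 71 per-subject features over
   twelve families: distributional moments and quantiles (incl. RMSSD),
   spectral and binary entropy, autocorrelation structure, tiled-window
   stability/lumpiness, flat spots, seasonal-trend decomposition strengths,
   KPSS/ADF stationarity, Teräsvirta nonlinearity, ARCH-LM and GARCH(1,1)
   heterogeneity, rescaled-range Hurst memory, Holt linear trend, and
   spectral band power. Day-level features are computed on wear-only
   minutes and aggregated across days by mean and SD.
3. **Stacked ensemble** — the severity target is the sum of per-item
   z-scores over the 20 GAD interview items. 100 lower-order gradient-boosted
   regressors, each on its own feature subset, feed two averaged boosted
   meta-regressors; nested 4-fold cross-validation makes every risk score an
   out-of-sample prediction (score(i) = mean of meta-models trained only on
   folds not containing i, over inner out-of-fold lower predictions).
4. **Risk evaluation** — Pearson and partial correlations with Fisher-z
   intervals (tanh(atanh r ± z·(n−3)^(−1/2))), MDD discriminant correlation,
   elevated-symptom classification (elevated ⇔ composite > mean + 1 SD) via
   rank-formulation AUC, Youden-J cutpoint and out-of-fold–calibrated Brier
   score, percentile odds-ratio curves (Haldane–Anscombe correction, Woolf
   intervals), and per-symptom correlation profiles.
5. **Synthetic cohort generator** — a tested module emulating the structure
   of a national actigraphy + diagnostic-interview cohort: a latent
   standard-normal GAD severity coupled to movement fragmentation,
   intensity and dispersion; graded item-response interviews with screener
   skip logic; a correlated latent MDD severity; and Beta-distributed wear
   compliance independent of severity, calibrated so ~55 % of subjects fail
   the half-week filter.

## Worked example

```r
library(actigad)

cfg <- run_config(cohort = list(n_subjects = 400, seed = 1), seed = 1)
res <- run_pipeline(cfg)
res$report
```

```
Risk-score evaluation (n = 162 )
  Continuum:           r = 0.608, CI [0.501, 0.697] 
  Partial (demogr.):   r = 0.607, CI [0.499, 0.696] 
  Discriminant (MDD):  r = 0.373, CI [0.232, 0.499] 
  Elevated symptoms:   AUC 0.895, sens 100.0%, spec 67.7%, Brier 0.115
  OR at >=90th pct:    12.730 CI [4.094, 39.584]
  No-symptom OR >=90th: 0.233 CI [0.078, 0.698]
  Strongest symptom correlations: anx_freq (0.60), out_of_mind (0.59), restless (0.58)
```

Reading this: of 400 simulated subjects, 162 wore the device at least half
the week and were analyzed. Their out-of-sample risk scores correlate
r = 0.61 with the observed symptom composite (essentially unchanged after
adjusting for demographics), correlate substantially less with the MDD
composite (discriminant validity), detect elevated symptoms with AUC 0.90,
and a subject at or above the 90th risk percentile has about 13× the odds
of elevated symptoms and about 0.23× the odds of reporting no symptoms at
all. The per-stage equivalents live in `analysis/01_simulate.R` …
`analysis/05_evaluate.R`, which write their artifacts under `results/`.

With movement coupling switched off (`effect_size_movement = 0`) the same
pipeline is calibrated: out-of-sample r ≈ 0, AUC ≈ 0.5 — the test suite
checks both behaviors across replicate seeds.

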