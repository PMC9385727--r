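Package: actigad
Title: Digital Phenotyping of Generalized Anxiety Symptom Severity from
    Wearable Actigraphy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers generalized anxiety disorder (GAD) symptom severity from
    one week of minute-epoch wearable movement data. Provides non-wear
    detection and compliance filtering for actigraphy count series, a
    catalog of per-subject time-series features (distributional, entropy,
    autocorrelation, tiled-window variance, seasonal-trend decomposition,
    stationarity, nonlinearity, GARCH heterogeneity, long-range memory,
    Holt linear trend, spectral band power), a stacked gradient-boosting
    ensemble with leakage-free out-of-fold predictions, and risk-score
    evaluation: continuum and partial correlations with Fisher-z intervals,
    elevated-symptom classification (ROC/AUC, Youden cutpoint, Brier
    score), percentile odds-ratio curves, and per-symptom correlation
    profiles. A synthetic cohort generator emulating the structure of a
    national actigraphy plus diagnostic-interview study makes the whole
    pipeline testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    rlang,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    pROC,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
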