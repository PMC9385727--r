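#!/usr/bin/env Rscript
# Stage 4 — score the GAD symptom composite (per-item z-scores summed over
# the included cohort) and fit the stacked gradient-boosting ensemble: 100
# lower-order boosted regressors on disjoint feature subsets feeding two
# averaged higher-order meta-regressors, nested 4-fold cross-validation, so
# every risk score is out-of-sample.
library(actigad)

seed <- 2026L
features <- read_feature_matrix("results/features.csv")
interviews <- as.data.frame(data.table::fread(
  "results/interviews.csv", colClasses = list(character = "subject_id")))
interviews <- interviews[match(features$subject_id, interviews$subject_id), ]

composites <- score_composite(interviews)
data.table::fwrite(composites, "results/composites.csv")

spec <- ensemble_spec(seed = seed)
predictions <- predict_risk(features, composites, spec)
write_predictions(predictions, "results/predictions.csv")

r <- cor(predictions$raw, composites$score)
cat(sprintf("Out-of-sample risk scores for %d subjects (4-fold CV).\n",
            nrow(predictions)))
cat(sprintf("Correlation with the observed composite: r = %.3f.\n", r))
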