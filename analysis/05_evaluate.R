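#!/usr/bin/env Rscript
# Stage 5 — evaluate the risk scores: continuum correlation with Fisher-z
# interval (marginal, partial given demographics, and MDD discriminant),
# elevated-symptom classification (ROC/AUC, Youden cutpoint, Brier score),
# percentile odds-ratio curves for elevated and for no symptoms, and the
# per-symptom correlation profile.
library(actigad)

read_csv_ids <- function(path) as.data.frame(data.table::fread(
  path, colClasses = list(character = "subject_id")))

predictions <- read_csv_ids("results/predictions.csv")
composites <- read_csv_ids("results/composites.csv")
interviews <- read_csv_ids("results/interviews.csv")
demographics <- read_csv_ids("results/demographics.csv")

report <- evaluate_risk(predictions, composites, interviews, demographics)
write_evaluation_report(report, "results/report.json")
print(report)
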