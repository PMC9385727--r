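# End-to-end orchestration: simulate (optional) -> read -> non-wear ->
# compliance filter -> features -> composite scoring -> ensemble ->
# evaluation, with one global seed fanned out deterministically per stage.

#' Pipeline configuration
#'
#' One object resolving every stage's parameters. May be built directly or
#' loaded from a YAML file with [load_run_config()].
#'
#' @param cohort a [cohort_config()] (used when simulating) or a list of its
#'   arguments.
#' @param nonwear a [nonwear_params()].
#' @param compliance_threshold inclusion threshold (default 0.5).
#' @param daily_window_minutes expected daily wear window (default 900).
#' @param valid_day_minutes minimum wear minutes per valid day (default 600).
#' @param families optional feature-family subset.
#' @param ensemble an [ensemble_spec()].
#' @param seed global seed; per-stage seeds derive from it deterministically.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = list(n_subjects = 300),
                       nonwear = nonwear_params(),
                       compliance_threshold = 0.5,
                       daily_window_minutes = 900,
                       valid_day_minutes = 600,
                       families = NULL,
                       ensemble = ensemble_spec(),
                       seed = 1L) {
  if (!inherits(cohort, "cohort_config")) {
    cohort$seed <- cohort$seed %||% stage_seed(seed, 1)
    cohort <- do.call(cohort_config, cohort)
  }
  if (!inherits(nonwear, "nonwear_params")) nonwear <- do.call(nonwear_params, nonwear)
  if (!inherits(ensemble, "ensemble_spec")) ensemble <- do.call(ensemble_spec, ensemble)
  ensemble$seed <- as.integer(stage_seed(seed, 4))
  structure(list(cohort = cohort, nonwear = nonwear,
                 compliance_threshold = compliance_threshold,
                 daily_window_minutes = daily_window_minutes,
                 valid_day_minutes = valid_day_minutes,
                 families = families, ensemble = ensemble,
                 seed = as.integer(seed)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a run configuration from YAML
#'
#' Nested keys mirror the [run_config()] arguments; unknown top-level keys
#' are rejected.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stopf("load_run_config: unknown keys: %s", paste(unknown, collapse = ", "))
  do.call(run_config, y)
}

#' Run the full pipeline
#'
#' Simulates a cohort (unless `cohort_data` supplies one), detects non-wear,
#' applies the compliance filter, extracts features for included subjects,
#' scores the symptom composite, fits the stacked ensemble for out-of-sample
#' risk predictions, and evaluates the risk scores. When `out_dir` is given,
#' every artifact (epoch CSV, wear report, feature matrix + sidecar,
#' predictions CSV, report JSON, manifest) is written there.
#'
#' @param config a [run_config()].
#' @param cohort_data optional precomputed output of [generate_cohort()] (or
#'   a compatible list with `series`, `interviews`, `demographics`).
#' @param out_dir optional artifact directory.
#' @return list of class `pipeline_result`: `report`, `predictions`,
#'   `features`, `composites`, `filter`, `cohort`.
#' @export
run_pipeline <- function(config = run_config(), cohort_data = NULL,
                         out_dir = NULL) {
  cohort <- cohort_data %||% generate_cohort(config$cohort)
  masks <- lapply(cohort$series, detect_nonwear, params = config$nonwear)
  filt <- compliance_filter(masks, config$compliance_threshold,
                            n_days = config$cohort$n_days,
                            daily_window_minutes = config$daily_window_minutes)
  if (length(filt$included) < config$ensemble$k_folds)
    stopf("run_pipeline: only %d subjects pass the compliance filter",
          length(filt$included))
  catalog <- feature_catalog(config$families)
  features <- build_feature_matrix(cohort$series, masks,
                                   subject_ids = filt$included,
                                   catalog = catalog,
                                   valid_day_minutes = config$valid_day_minutes)
  intv <- cohort$interviews[match(filt$included, cohort$interviews$subject_id), ]
  composites <- score_composite(intv)
  predictions <- predict_risk(features, composites, config$ensemble)
  report <- evaluate_risk(predictions, composites, intv, cohort$demographics)
  result <- structure(list(report = report, predictions = predictions,
                           features = features, composites = composites,
                           filter = filt, cohort = cohort, config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_epoch_table(result$cohort$series, file.path(out_dir, "epochs.csv"))
  data.table::fwrite(result$cohort$interviews, file.path(out_dir, "interviews.csv"))
  data.table::fwrite(result$cohort$demographics, file.path(out_dir, "demographics.csv"))
  data.table::fwrite(result$filter$report, file.path(out_dir, "wear_report.csv"))
  write_feature_matrix(result$features, file.path(out_dir, "features.csv"),
                       meta = list(valid_day_minutes = result$config$valid_day_minutes,
                                   gap_policy = "concatenate",
                                   decomposition = "ma"))
  write_predictions(result$predictions, file.path(out_dir, "predictions.csv"))
  write_evaluation_report(result$report, file.path(out_dir, "report.json"))
  manifest <- list(
    seed = result$config$seed,
    config_hash = rlang::hash(result$config),
    n_subjects = result$config$cohort$n_subjects,
    n_included = length(result$filter$included),
    package_version = as.character(utils::packageVersion("actigad")),
    r_version = R.version.string,
    created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
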