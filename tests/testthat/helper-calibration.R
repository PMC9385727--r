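# Full-pipeline calibration runs under the generator's study conditions,
# cached so several tests can share one set of runs. Cohorts of 200 subjects
# (before compliance attrition) keep the replicate set inside a practical
# runtime; the methods vignette documents the problem sizes used.
calibration_runs <- local({
  cache <- new.env(parent = emptyenv())
  function(kind = c("null", "planted"), n_seeds = 10, n_subjects = 200) {
    kind <- match.arg(kind)
    key <- paste(kind, n_seeds, n_subjects)
    if (!is.null(cache[[key]])) return(cache[[key]])
    runs <- lapply(seq_len(n_seeds), function(s) {
      cohort_args <- list(n_subjects = n_subjects, seed = 30000 + s)
      if (kind == "null") cohort_args$effect_size_movement <- 0
      cfg <- run_config(cohort = cohort_args, seed = 30000 + s)
      res <- run_pipeline(cfg)
      list(r = res$report$r_continuum$r,
           ci_lower = res$report$r_continuum$ci_lower,
           ci_upper = res$report$r_continuum$ci_upper,
           auc = res$report$auc,
           r_mdd = res$report$r_discriminant_mdd$r,
           n_included = res$report$n)
    })
    cache[[key]] <- runs
    runs
  }
})
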