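# Risk-score evaluation: continuum/partial/discriminant correlations with
# Fisher-z intervals, elevated-symptom classification (ROC/AUC, Youden
# cutpoint, Brier score), percentile odds-ratio curves, and per-symptom
# correlation profiles.

#' Pearson correlation with Fisher-z confidence interval
#'
#' The interval is `tanh(atanh(r) +/- z_{1-alpha/2} / sqrt(n - 3))`, with the
#' atanh argument clamped just inside (-1, 1) so perfectly correlated inputs
#' do not overflow.
#'
#' @param x,y numeric vectors, or pass `r` and `n` directly.
#' @param alpha two-sided level (default 0.05).
#' @param r,n optionally supply a precomputed correlation and sample size.
#' @return list `r`, `ci_lower`, `ci_upper`, `n`.
#' @export
pearson_ci <- function(x = NULL, y = NULL, alpha = 0.05, r = NULL, n = NULL) {
  if (is.null(r)) {
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 4) stopf("pearson_ci: need n >= 4")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stopf("pearson_ci: constant input")
    r <- stats::cor(x, y)
  }
  if (n < 4) stopf("pearson_ci: need n >= 4")
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - alpha / 2)
  list(r = r, ci_lower = tanh(z - q * se), ci_upper = tanh(z + q * se), n = n)
}

#' Partial correlation with Fisher-z interval
#'
#' Residualizes `x` and `y` on the covariates (linear model; character and
#' factor covariates dummy-coded) and correlates the residuals. By default
#' the interval uses the unadjusted standard error `1/sqrt(n - 3)`; set
#' `adjust_df = TRUE` for `1/sqrt(n - 3 - p)` with `p` covariate columns.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame of covariates.
#' @param alpha two-sided level.
#' @param adjust_df adjust the Fisher SE for covariate degrees of freedom.
#' @return list `r`, `ci_lower`, `ci_upper`, `n`.
#' @export
partial_correlation_ci <- function(x, y, covariates, alpha = 0.05,
                                   adjust_df = FALSE) {
  covariates <- as.data.frame(covariates)
  ok <- stats::complete.cases(x, y, covariates)
  x <- x[ok]; y <- y[ok]
  covariates <- covariates[ok, , drop = FALSE]
  mm <- stats::model.matrix(~ ., data = covariates)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm))
    stopf("partial_correlation_ci: collinear covariates (%s)",
          paste(colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]], collapse = ", "))
  n <- length(x)
  p <- ncol(mm) - 1
  if (n <= p + 3) stopf("partial_correlation_ci: n too small for covariates")
  rx <- qr.resid(qr_mm, x)
  ry <- qr.resid(qr_mm, y)
  # a variable fully explained by the covariates leaves only numerical noise;
  # its partial correlation is zero, not an artifact of that noise
  degenerate <- stats::sd(rx) < 1e-10 * max(1, stats::sd(x)) ||
    stats::sd(ry) < 1e-10 * max(1, stats::sd(y))
  r <- if (degenerate) 0 else stats::cor(rx, ry)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  se <- if (adjust_df) 1 / sqrt(n - 3 - p) else 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - alpha / 2)
  list(r = r, ci_lower = tanh(z - q * se), ci_upper = tanh(z + q * se), n = n)
}

#' Flag elevated symptom severity
#'
#' Elevated means a composite score strictly greater than the cohort mean
#' plus one SD (sample statistics of the supplied cohort).
#'
#' @param composites data.frame `subject_id`, `score`.
#' @param n_sd number of SDs above the mean (default 1).
#' @return data.frame `subject_id`, `elevated`.
#' @export
flag_elevated <- function(composites, n_sd = 1) {
  if (nrow(composites) < 2) stopf("flag_elevated: need at least 2 subjects")
  s <- stats::sd(composites$score)
  if (s == 0) {
    warnf("flag_elevated: zero variance; no subject flagged")
    return(data.frame(subject_id = composites$subject_id, elevated = FALSE,
                      stringsAsFactors = FALSE))
  }
  thr <- mean(composites$score) + n_sd * s
  data.frame(subject_id = composites$subject_id,
             elevated = composites$score > thr, stringsAsFactors = FALSE)
}

#' ROC curve and AUC
#'
#' AUC by the rank (concordance) formulation with tie correction; ROC points
#' at every distinct score threshold.
#'
#' @param scores numeric risk scores.
#' @param flags logical/0-1 outcomes (both classes required).
#' @return list `auc` and `roc` (data.frame `threshold`, `sensitivity`,
#'   `specificity`).
#' @export
roc_auc <- function(scores, flags) {
  flags <- as.logical(flags)
  n1 <- sum(flags); n0 <- sum(!flags)
  if (n1 == 0 || n0 == 0) stopf("roc_auc: both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[flags]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(scores[flags] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!flags] < t), numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), sensitivity = c(0, sens),
                    specificity = c(1, spec))
  list(auc = auc, roc = roc)
}

#' Optimal cutpoint by Youden's J
#'
#' Maximizes `J = sensitivity + specificity - 1`; ties are broken toward the
#' higher specificity.
#'
#' @param roc ROC data.frame from [roc_auc()].
#' @return list `threshold`, `sensitivity`, `specificity`, `youden_j`.
#' @export
optimal_cutpoint <- function(roc) {
  j <- roc$sensitivity + roc$specificity - 1
  cand <- which(j == max(j))
  best <- cand[which.max(roc$specificity[cand])]
  list(threshold = roc$threshold[best], sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best], youden_j = j[best])
}

#' Brier score
#'
#' Mean squared difference between predicted probability and binary outcome.
#'
#' @param probabilities numeric in \[0, 1\].
#' @param flags logical/0-1 outcomes.
#' @return numeric scalar.
#' @export
brier_score <- function(probabilities, flags) {
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE))
    stopf("brier_score: probabilities must lie in [0, 1]")
  mean((probabilities - as.numeric(flags))^2)
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = ad / bc` on the 2x2 table; when any cell is zero the
#' Haldane-Anscombe +0.5 correction is applied to every cell, and the Woolf
#' interval `exp(log OR +/- z * sqrt(sum of reciprocal cells))` is computed
#' on the corrected table.
#'
#' @param a,b,c,d cell counts: exposed/outcome, exposed/no-outcome,
#'   unexposed/outcome, unexposed/no-outcome.
#' @param alpha two-sided level.
#' @return list `or`, `ci_lower`, `ci_upper`.
#' @export
odds_ratio_ci <- function(a, b, c, d, alpha = 0.05) {
  cells <- c(a, b, c, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  q <- stats::qnorm(1 - alpha / 2)
  list(or = or, ci_lower = exp(log(or) - q * se), ci_upper = exp(log(or) + q * se))
}

#' Percentile odds-ratio curve
#'
#' For each percentile threshold t, tabulates (risk percentile >= t) against
#' the outcome and reports the odds ratio with its Woolf 95\% interval.
#' Thresholds with an empty exposure arm yield missing values.
#'
#' @param percentiles numeric risk percentiles (0-100].
#' @param flags logical outcome (e.g. elevated symptoms, or no symptoms for
#'   the inverse curve).
#' @param thresholds percentile thresholds (default 1..99).
#' @param alpha two-sided level.
#' @return data.frame `threshold`, `or`, `ci_lower`, `ci_upper`.
#' @export
or_curve <- function(percentiles, flags, thresholds = 1:99, alpha = 0.05) {
  flags <- as.logical(flags)
  if (length(unique(flags)) < 2) stopf("or_curve: both outcome classes required")
  rows <- lapply(thresholds, function(t) {
    hi <- percentiles >= t
    if (!any(hi) || all(hi))
      return(data.frame(threshold = t, or = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_))
    a <- sum(hi & flags); b <- sum(hi & !flags)
    c <- sum(!hi & flags); d <- sum(!hi & !flags)
    o <- odds_ratio_ci(a, b, c, d, alpha)
    data.frame(threshold = t, or = o$or, ci_lower = o$ci_lower,
               ci_upper = o$ci_upper)
  })
  do.call(rbind, rows)
}

#' Per-symptom correlation profile
#'
#' Pearson correlation (point-biserial for binary items) of the risk score
#' with each interview item, each with a Fisher-z interval. Zero-variance
#' items are reported missing with a range-restriction flag.
#'
#' @param scores numeric risk scores aligned to `interviews` rows.
#' @param interviews interview data.frame.
#' @param items item columns (default the 20 GAD items).
#' @return data.frame `item`, `r`, `ci_lower`, `ci_upper`, `range_restricted`.
#' @export
symptom_correlation_profile <- function(scores, interviews,
                                        items = default_item_params()$item) {
  rows <- lapply(items, function(it) {
    v <- interviews[[it]]
    if (stats::sd(v) == 0)
      return(data.frame(item = it, r = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, range_restricted = TRUE))
    ci <- pearson_ci(scores, v)
    data.frame(item = it, r = ci$r, ci_lower = ci$ci_lower,
               ci_upper = ci$ci_upper, range_restricted = FALSE)
  })
  do.call(rbind, rows)
}

#' Full evaluation report
#'
#' Runs the four evaluation procedures on a prediction table: continuum
#' correlation (with partial correlation given demographics, and the MDD
#' discriminant correlation), elevated-symptom classification at the Youden
#' cutpoint with Brier score, percentile odds-ratio curves (elevated and
#' no-symptom outcomes), and the per-symptom correlation profile.
#'
#' @param predictions data.frame from [predict_risk()].
#' @param composites GAD composites (`subject_id`, `score`).
#' @param interviews interview data.frame (for the MDD composite, the
#'   no-symptom flags and the symptom profile).
#' @param demographics data.frame with `subject_id`, `age`, `gender`,
#'   `ethnicity` (optional; partial correlation skipped when absent).
#' @param alpha two-sided level.
#' @return list of class `evaluation_report`.
#' @export
evaluate_risk <- function(predictions, composites, interviews,
                          demographics = NULL, alpha = 0.05) {
  ids <- predictions$subject_id
  comp <- composites[match(ids, composites$subject_id), ]
  intv <- interviews[match(ids, interviews$subject_id), ]
  r_cont <- pearson_ci(predictions$raw, comp$score, alpha)
  r_mdd <- pearson_ci(predictions$raw, intv$mdd_composite, alpha)
  r_part <- NULL
  if (!is.null(demographics)) {
    demo <- demographics[match(ids, demographics$subject_id), ]
    r_part <- partial_correlation_ci(predictions$raw, comp$score,
                                     demo[, c("age", "gender", "ethnicity")],
                                     alpha)
  }
  flags <- flag_elevated(comp)$elevated
  roc <- roc_auc(predictions$percentile, flags)
  cut <- optimal_cutpoint(roc$roc)
  brier <- brier_score(predictions$probability, flags)
  orc <- or_curve(predictions$percentile, flags, alpha = alpha)
  nosym <- no_symptom_flags(intv)
  orc_ns <- if (length(unique(nosym)) == 2)
    or_curve(predictions$percentile, nosym, alpha = alpha) else NULL
  profile <- symptom_correlation_profile(predictions$raw, intv)
  structure(list(
    r_continuum = r_cont, r_partial = r_part, r_discriminant_mdd = r_mdd,
    auc = roc$auc, roc = roc$roc, cutpoint = cut, brier = brier,
    or_curve = orc, no_symptom_or_curve = orc_ns,
    symptom_correlations = profile, n = length(ids)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  fmt_ci <- function(ci) sprintf("r = %.3f, CI [%.3f, %.3f]", ci$r, ci$ci_lower, ci$ci_upper)
  cat("Risk-score evaluation (n =", x$n, ")\n")
  cat("  Continuum:          ", fmt_ci(x$r_continuum), "\n")
  if (!is.null(x$r_partial))
    cat("  Partial (demogr.):  ", fmt_ci(x$r_partial), "\n")
  cat("  Discriminant (MDD): ", fmt_ci(x$r_discriminant_mdd), "\n")
  cat(sprintf("  Elevated symptoms:   AUC %.3f, sens %.1f%%, spec %.1f%%, Brier %.3f\n",
              x$auc, 100 * x$cutpoint$sensitivity, 100 * x$cutpoint$specificity,
              x$brier))
  or90 <- x$or_curve[x$or_curve$threshold == 90, ]
  if (nrow(or90) && is.finite(or90$or))
    cat(sprintf("  OR at >=90th pct:    %.3f CI [%.3f, %.3f]\n",
                or90$or, or90$ci_lower, or90$ci_upper))
  if (!is.null(x$no_symptom_or_curve)) {
    ns90 <- x$no_symptom_or_curve[x$no_symptom_or_curve$threshold == 90, ]
    if (nrow(ns90) && is.finite(ns90$or))
      cat(sprintf("  No-symptom OR >=90th: %.3f CI [%.3f, %.3f]\n",
                  ns90$or, ns90$ci_lower, ns90$ci_upper))
  }
  top <- x$symptom_correlations[order(-x$symptom_correlations$r), ]
  cat("  Strongest symptom correlations:",
      paste(utils::head(top$item, 3), sprintf("(%.2f)", utils::head(top$r, 3)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an evaluation report to JSON (+ CSV companions)
#'
#' @param report an `evaluation_report`.
#' @param path JSON path; OR-curve and symptom-profile CSVs are written
#'   alongside with `_or_curve.csv` / `_symptoms.csv` suffixes.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  core <- list(
    r_continuum = report$r_continuum, r_partial = report$r_partial,
    r_discriminant_mdd = report$r_discriminant_mdd, auc = report$auc,
    cutpoint = report$cutpoint, brier = report$brier, n = report$n)
  jsonlite::write_json(core, path, auto_unbox = TRUE, digits = NA, null = "null")
  base <- sub("\\.json$", "", path)
  data.table::fwrite(report$or_curve, paste0(base, "_or_curve.csv"))
  if (!is.null(report$no_symptom_or_curve))
    data.table::fwrite(report$no_symptom_or_curve, paste0(base, "_no_symptom_or_curve.csv"))
  data.table::fwrite(report$symptom_correlations, paste0(base, "_symptoms.csv"))
  invisible(path)
}
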