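# Stacked gradient-boosting ensemble: 100 lower-order boosted regressors on
# disjoint feature subsets feed two higher-order boosted meta-regressors
# (averaged), with nested 4-fold cross-validation so every risk score is a
# genuinely out-of-sample prediction.

#' Composite symptom severity scores
#'
#' Each item is z-scored across the supplied (included) cohort and the
#' z-scores are summed. Items with zero variance contribute 0 to everyone.
#'
#' @param interviews interview data.frame (one row per subject).
#' @param items item columns to use (default the 20 GAD items).
#' @return data.frame `subject_id`, `score`.
#' @export
score_composite <- function(interviews, items = default_item_params()$item) {
  if (nrow(interviews) == 0) stopf("score_composite: empty cohort")
  m <- as.matrix(interviews[, items, drop = FALSE])
  z <- apply(m, 2, function(col) {
    s <- stats::sd(col)
    if (!is.finite(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  data.frame(subject_id = interviews$subject_id, score = unname(rowSums(z)),
             stringsAsFactors = FALSE)
}

#' Ensemble specification
#'
#' @param n_lower number of lower-order models (default 100; capped at the
#'   number of features).
#' @param n_meta number of higher-order meta-models to average (default 2;
#'   they differ by seed and tree depth).
#' @param k_folds outer (and inner) cross-validation folds (default 4).
#' @param lower_params,meta_params booster hyperparameters
#'   (learning rate `eta`, `max_depth`, `nrounds`, `subsample`).
#' @param seed integer seed controlling folds, feature partition and boosters.
#' @return object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_lower = 100, n_meta = 2, k_folds = 4,
                          lower_params = list(eta = 0.1, max_depth = 2,
                                              nrounds = 60, subsample = 1),
                          meta_params = list(eta = 0.05, max_depth = c(2, 3),
                                             nrounds = 150, subsample = 1),
                          seed = 1L) {
  if (n_lower < 1) stopf("ensemble_spec: n_lower must be >= 1")
  if (n_meta < 1) stopf("ensemble_spec: n_meta must be >= 1")
  if (k_folds < 2) stopf("ensemble_spec: k_folds must be >= 2")
  structure(list(n_lower = as.integer(n_lower), n_meta = as.integer(n_meta),
                 k_folds = as.integer(k_folds), lower_params = lower_params,
                 meta_params = meta_params, seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Random fold assignment
#'
#' Folds are as equal-sized as possible, assigned by a seeded shuffle with no
#' stratification.
#'
#' @param subject_ids character ids.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold labels (1..k) named by subject id.
#' @export
assign_folds <- function(subject_ids, k, seed) {
  n <- length(subject_ids)
  if (k > n) stopf("assign_folds: k (%d) exceeds number of subjects (%d)", k, n)
  with_local_seed(seed, {
    lab <- rep(seq_len(k), length.out = n)[sample.int(n)]
    stats::setNames(lab, subject_ids)
  })
}

#' Partition features across lower-order models
#'
#' Features are shuffled deterministically and dealt round-robin into
#' `min(n_lower, n_features)` non-empty disjoint subsets; alternatively the
#' partition can be blocked by feature family (prefix before the first dot).
#'
#' @param feature_names character vector.
#' @param n_lower requested number of subsets.
#' @param seed integer seed.
#' @param by_family block by family instead of dealing round-robin.
#' @return list of disjoint character vectors whose union is `feature_names`.
#' @export
partition_features <- function(feature_names, n_lower, seed, by_family = FALSE) {
  if (length(feature_names) == 0) stopf("partition_features: empty catalog")
  if (by_family) {
    fam <- sub("\\..*$", "", feature_names)
    return(split(feature_names, fam))
  }
  k <- min(n_lower, length(feature_names))
  with_local_seed(seed, {
    shuffled <- sample(feature_names)
    split(shuffled, rep(seq_len(k), length.out = length(shuffled)))
  })
}

# single deterministic booster fit
fit_booster <- function(X, y, params, nrounds, seed) {
  d <- xgboost::xgb.DMatrix(X, label = y, missing = NA)
  p <- c(params, list(objective = "reg:squarederror", nthread = 1,
                      seed = as.integer(seed %% 2147483647)))
  xgboost::xgb.train(p, d, nrounds = nrounds, verbose = 0)
}

predict_booster <- function(model, X) {
  as.numeric(stats::predict(model, xgboost::xgb.DMatrix(X, missing = NA)))
}

#' Leakage-free out-of-sample risk predictions
#'
#' For each outer fold: (i) inner out-of-fold predictions of every lower
#' model (a boosted regressor on its feature subset; the booster handles
#' missing values natively) are generated within the training folds;
#' (ii) `n_meta` boosted meta-regressors (differing in seed and depth) are
#' trained on the inner out-of-fold prediction matrix; (iii) lower models are
#' refit on all training folds; (iv) held-out subjects get the average of
#' the meta-model outputs as their raw risk score. No model contributing to
#' a subject's score ever saw that subject's target.
#'
#' @param features feature matrix data.frame (from [build_feature_matrix()])
#'   or a numeric matrix with rownames; non-feature columns `subject_id` and
#'   `n_valid_days` are dropped.
#' @param targets data.frame `subject_id`, `score` (see [score_composite()])
#'   or a named numeric vector.
#' @param spec an [ensemble_spec()].
#' @return data.frame `subject_id`, `raw`, `fold`, in the input subject order.
#' @export
fit_oof_predictions <- function(features, targets, spec = ensemble_spec()) {
  if (is.data.frame(features)) {
    ids <- features$subject_id
    X <- as.matrix(features[, setdiff(names(features), c("subject_id", "n_valid_days")),
                            drop = FALSE])
    rownames(X) <- ids
  } else {
    X <- features
    ids <- rownames(X)
  }
  if (is.data.frame(targets)) {
    y <- stats::setNames(targets$score, targets$subject_id)
  } else y <- targets
  if (is.null(ids) || !all(ids %in% names(y)))
    stopf("fit_oof_predictions: features and targets are misaligned")
  y <- y[ids]
  if (anyNA(y)) stopf("fit_oof_predictions: missing targets")
  if (stats::sd(y) == 0)
    stopf("fit_oof_predictions: constant target, undefined learning problem")
  n <- length(ids)
  # canonical ordering makes predictions invariant to row/column order
  folds <- assign_folds(sort(ids), spec$k_folds, stage_seed(spec$seed, 1))[ids]
  subsets <- partition_features(sort(colnames(X)), spec$n_lower,
                                stage_seed(spec$seed, 2))
  L <- length(subsets)
  lp <- spec$lower_params
  mp <- spec$meta_params
  meta_depths <- rep(mp$max_depth, length.out = spec$n_meta)
  raw <- stats::setNames(rep(NA_real_, n), ids)
  for (f in seq_len(spec$k_folds)) {
    tr <- sort(ids[folds != f])
    te <- sort(ids[folds == f])
    ytr <- y[tr]
    inner <- assign_folds(tr, spec$k_folds, stage_seed(spec$seed, 100 + f))
    Ztr <- matrix(NA_real_, length(tr), L, dimnames = list(tr, NULL))
    for (s in seq_len(L)) {
      Xs <- X[tr, subsets[[s]], drop = FALSE]
      for (g in seq_len(spec$k_folds)) {
        itr <- inner != g
        m <- fit_booster(Xs[itr, , drop = FALSE], ytr[itr],
                         list(eta = lp$eta, max_depth = lp$max_depth,
                              subsample = lp$subsample),
                         lp$nrounds, stage_seed(spec$seed, 1000 + f * 37 + s))
        Ztr[!itr, s] <- predict_booster(m, Xs[!itr, , drop = FALSE])
      }
    }
    metas <- lapply(seq_len(spec$n_meta), function(j)
      fit_booster(Ztr, ytr,
                  list(eta = mp$eta, max_depth = meta_depths[j],
                       subsample = mp$subsample),
                  mp$nrounds, stage_seed(spec$seed, 5000 + f * 13 + j)))
    Zte <- matrix(NA_real_, length(te), L, dimnames = list(te, NULL))
    for (s in seq_len(L)) {
      m <- fit_booster(X[tr, subsets[[s]], drop = FALSE], ytr,
                       list(eta = lp$eta, max_depth = lp$max_depth,
                            subsample = lp$subsample),
                       lp$nrounds, stage_seed(spec$seed, 2000 + f * 37 + s))
      Zte[, s] <- predict_booster(m, X[te, subsets[[s]], drop = FALSE])
    }
    preds <- vapply(metas, function(m) predict_booster(m, Zte), numeric(length(te)))
    if (is.null(dim(preds))) preds <- matrix(preds, nrow = length(te))
    raw[te] <- rowMeans(preds)
  }
  data.frame(subject_id = ids, raw = unname(raw),
             fold = unname(folds[ids]), stringsAsFactors = FALSE)
}

#' Percentile-normalize risk scores
#'
#' `percentile = 100 * mean rank / n`; ties share their average rank, so the
#' transform is monotone in the raw score.
#'
#' @param raw numeric scores.
#' @return numeric percentiles in (0, 100].
#' @export
percentile_normalize <- function(raw) {
  if (length(raw) < 2) stopf("percentile_normalize: need at least 2 subjects")
  100 * rank(raw, ties.method = "average") / length(raw)
}

#' Out-of-fold probability calibration
#'
#' Within each outer fold, a univariate logistic regression of the elevated
#' flag on the raw risk score is fitted on the training subjects and applied
#' to the held-out subjects. A single-class training fold falls back to the
#' training prevalence.
#'
#' @param raw numeric raw scores.
#' @param flags logical/0-1 outcome flags.
#' @param folds integer fold labels aligned to `raw`.
#' @return numeric probabilities in \[0, 1\].
#' @export
calibrate_probability <- function(raw, flags, folds) {
  flags <- as.integer(flags)
  prob <- rep(NA_real_, length(raw))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(flags[tr])) < 2) {
      prob[!tr] <- mean(flags[tr])
      next
    }
    fit <- suppressWarnings(stats::glm(flags[tr] ~ raw[tr], family = stats::binomial()))
    eta <- stats::coef(fit)[1] + stats::coef(fit)[2] * raw[!tr]
    prob[!tr] <- stats::plogis(eta)
  }
  pmin(pmax(prob, 0), 1)
}

#' Full risk prediction table
#'
#' Convenience wrapper: out-of-fold raw scores, cohort percentiles, and
#' out-of-fold calibrated probabilities of the elevated flag.
#'
#' @param features,targets,spec as in [fit_oof_predictions()].
#' @param flags logical elevated flags named by subject id (default: derived
#'   from `targets` via [flag_elevated()]).
#' @return data.frame `subject_id`, `raw`, `percentile`, `probability`, `fold`.
#' @export
predict_risk <- function(features, targets, spec = ensemble_spec(), flags = NULL) {
  oof <- fit_oof_predictions(features, targets, spec)
  oof$percentile <- percentile_normalize(oof$raw)
  if (is.null(flags)) {
    fl <- flag_elevated(targets)
    flags <- stats::setNames(fl$elevated, fl$subject_id)
  }
  oof$probability <- calibrate_probability(oof$raw, flags[oof$subject_id], oof$fold)
  oof[, c("subject_id", "raw", "percentile", "probability", "fold")]
}

#' Write risk predictions to CSV
#' @param predictions prediction data.frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  data.table::fwrite(predictions, path)
  invisible(path)
}
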