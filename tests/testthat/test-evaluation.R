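test_that("Fisher-z intervals are correct and robust at the boundary", {
  ci <- pearson_ci(r = 0.3, n = 100)
  z <- atanh(0.3); se <- 1 / sqrt(97)
  expect_equal(ci$ci_lower, tanh(z - qnorm(0.975) * se))
  expect_equal(ci$ci_upper, tanh(z + qnorm(0.975) * se))
  x <- 1:50
  ci1 <- pearson_ci(x, x)
  expect_equal(ci1$r, 1)
  expect_true(is.finite(ci1$ci_lower) && ci1$ci_upper <= 1)
  expect_error(pearson_ci(1:10, rep(2, 10)), "constant")
})

test_that("Fisher CI coverage is near nominal under the null", {
  set.seed(12)
  n <- 264
  cover <- vapply(1:1000, function(i) {
    x <- rnorm(n); y <- rnorm(n)
    ci <- pearson_ci(x, y)
    ci$ci_lower > 0 || ci$ci_upper < 0
  }, logical(1))
  expect_gte(mean(cover), 0.03)
  expect_lte(mean(cover), 0.07)
})

test_that("partial correlation residualizes covariates correctly", {
  set.seed(13)
  n <- 300
  covs <- data.frame(age = runif(n, 20, 39),
                     gender = sample(c("f", "m"), n, TRUE),
                     ethnicity = sample(letters[1:4], n, TRUE))
  # covariates independent of x and y: partial ~ marginal
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  pc <- partial_correlation_ci(x, y, covs)
  expect_lt(abs(pc$r - cor(x, y)), 0.05)
  # y identical to a covariate: partial correlation collapses to noise
  pc2 <- partial_correlation_ci(x, covs$age, covs)
  expect_lt(abs(pc2$r), 0.05)
  covs2 <- covs; covs2$age2 <- covs$age * 2
  expect_error(partial_correlation_ci(x, y, covs2), "collinear")
})

test_that("elevated flags use the mean-plus-SD rule", {
  comp <- data.frame(subject_id = letters[1:4], score = c(0, 0, 0, 10))
  fl <- flag_elevated(comp)
  expect_identical(fl$elevated, c(FALSE, FALSE, FALSE, TRUE))
  set.seed(14)
  big <- data.frame(subject_id = seq_len(20000), score = rnorm(20000))
  frac <- mean(flag_elevated(big)$elevated)
  expect_lt(abs(frac - pnorm(1, lower.tail = FALSE)), 0.01)
  expect_warning(fl0 <- flag_elevated(data.frame(subject_id = 1:3, score = rep(1, 3))),
                 "zero variance")
  expect_false(any(fl0$elevated))
})

test_that("AUC matches pair enumeration, ties and the trapezoid identity", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(oracle_trapezoid_auc(r$roc), 0.75)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(15)
  for (i in 1:20) {
    sc <- sample(1:8, 60, TRUE)  # plenty of ties
    fl <- rbinom(60, 1, 0.4)
    if (length(unique(fl)) < 2) next
    r <- roc_auc(sc, fl)
    expect_equal(oracle_trapezoid_auc(r$roc), r$auc, tolerance = 1e-12)
  }
  null_auc <- roc_auc(rnorm(2000), rbinom(2000, 1, 0.5))$auc
  expect_gt(null_auc, 0.45); expect_lt(null_auc, 0.55)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("rank-formulation AUC agrees with an independent ROC library", {
  set.seed(151)
  for (i in 1:15) {
    sc <- if (i %% 2) rnorm(80) else sample(1:6, 80, TRUE)
    fl <- rbinom(80, 1, 0.4)
    if (length(unique(fl)) < 2) next
    ours <- roc_auc(sc, fl)$auc
    ref <- suppressMessages(as.numeric(pROC::auc(fl, sc, direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("Youden cutpoint separates separable classes", {
  r <- roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  cut <- optimal_cutpoint(r$roc)
  expect_equal(cut$sensitivity, 1)
  expect_equal(cut$specificity, 1)
  expect_equal(cut$youden_j, 1)
  expect_gt(cut$threshold, 2)
  expect_lte(cut$threshold, 3)
})

test_that("Brier score identities hold", {
  expect_equal(brier_score(c(1, 0), c(1, 0)), 0)
  expect_equal(brier_score(rep(0.5, 10), rbinom(10, 1, 0.5)), 0.25)
  set.seed(16)
  fl <- rbinom(4000, 1, 0.22)
  p <- mean(fl)
  expect_equal(brier_score(rep(p, 4000), fl), p * (1 - p), tolerance = 1e-12)
  expect_error(brier_score(c(1.2, 0.1), c(1, 0)), "probabilities")
})

test_that("odds ratios and Woolf intervals match the printed 2x2 example", {
  o <- odds_ratio_ci(8, 2, 12, 78)
  expect_equal(o$or, 26.0)
  se <- sqrt(1 / 8 + 1 / 2 + 1 / 12 + 1 / 78)
  expect_equal(o$ci_lower, exp(log(26) - qnorm(0.975) * se))
  expect_equal(o$ci_upper, exp(log(26) + qnorm(0.975) * se))
  expect_equal(round(o$ci_lower, 2), 4.92)
  expect_equal(o$ci_upper, 137.5, tolerance = 2e-3)
  # zero cells engage the Haldane-Anscombe correction
  o0 <- odds_ratio_ci(5, 0, 3, 10)
  expect_true(is.finite(o0$or) && is.finite(o0$ci_upper))
})

test_that("OR curves fluctuate around 1 under independence and ignore order", {
  set.seed(17)
  pct <- percentile_normalize(rnorm(2000))
  fl <- rbinom(2000, 1, 0.3)
  curve <- or_curve(pct, fl)
  expect_true(all(is.finite(curve$or)))
  expect_lt(abs(mean(log(curve$or))), 0.25)
  perm <- sample(2000)
  curve2 <- or_curve(pct[perm], fl[perm])
  expect_equal(curve, curve2)
  expect_error(or_curve(pct, rep(1, 2000)), "both outcome classes")
})

test_that("symptom profiles rank discriminating items first", {
  coh <- small_cohort(n = 60)
  intv <- coh$interviews
  th <- coh$latent$theta_gad
  prof <- symptom_correlation_profile(th, intv)
  expect_identical(prof$item, default_item_params()$item)
  expect_true(all(prof$r[!prof$range_restricted] > 0))
  # an item equal in sign pattern to the score correlates near 1
  intv2 <- intv
  intv2$restless <- as.integer(th > median(th))
  prof2 <- symptom_correlation_profile(as.numeric(th > median(th)), intv2)
  expect_gt(prof2$r[prof2$item == "restless"], 0.99)
  intv2$tense <- 1L
  prof3 <- symptom_correlation_profile(th, intv2)
  expect_true(prof3$range_restricted[prof3$item == "tense"])
  expect_true(is.na(prof3$r[prof3$item == "tense"]))
})

test_that("high-discrimination items dominate the symptom profile", {
  ip <- default_item_params()
  ip$a[] <- 0.4
  ip$a[ip$item == "keyed_up"] <- 3.0
  ip$a[ip$item == "anx_1mo"] <- 5
  ip$b[ip$item == "anx_1mo"] <- -8  # screener effectively always passed
  wins <- vapply(1:40, function(s) {
    cfg <- cohort_config(n_subjects = 150, item_params = ip, seed = 7000 + s)
    lat <- generate_latent_profiles(cfg, seed = 7000 + s)
    set.seed(8000 + s)
    intv <- do.call(rbind, lapply(seq_len(150), function(i)
      generate_interview(lat[i, ], cfg)))
    prof <- symptom_correlation_profile(lat$theta_gad, intv)
    r_target <- prof$r[prof$item == "keyed_up"]
    all(r_target >= prof$r[!prof$item %in% c("keyed_up", "anx_1mo")], na.rm = TRUE)
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})
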