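test_that("distributional features match hand arithmetic and closed forms", {
  f <- distributional_features(c(1, 2, 3))
  expect_equal(unname(f["mean"]), 2)
  expect_equal(unname(f["sd"]), 1)
  expect_equal(unname(f["rmssd"]), 1)
  f <- distributional_features(rep(4.2, 50))
  expect_equal(unname(f["sd"]), 0)
  expect_equal(unname(f["rmssd"]), 0)
  expect_equal(unname(f[c("q10", "q30", "q70", "q90")]), rep(4.2, 4))
  f <- distributional_features(0:99)
  expect_equal(unname(f["q10"]), 9.9)
  expect_equal(unname(f["q90"]), 89.1)
  expect_true(all(is.na(distributional_features(5)[-1])))
})

test_that("entropy features separate tones from noise", {
  expect_equal(unname(entropy_features(rep(3, 100))["binary_entropy"]), 0)
  set.seed(1)
  tone <- sin(2 * pi * (1:4096) * 16 / 4096)
  expect_lt(unname(entropy_features(tone)["spectral_entropy"]), 0.2)
  noise <- rnorm(4096)
  expect_gt(unname(entropy_features(noise)["spectral_entropy"]), 0.9)
  expect_true(is.na(entropy_features(rep(3, 100))["spectral_entropy"]))
})

test_that("autocorrelation features track the generating process", {
  set.seed(2)
  iid <- rnorm(10000)
  expect_lt(abs(autocorr_features(iid)["acf1"]), 0.05)
  ar1 <- as.numeric(arima.sim(list(ar = 0.8), 10000))
  a <- autocorr_features(ar1)["acf1"]
  expect_gt(a, 0.75); expect_lt(a, 0.85)
  alt <- rep(c(1, -1), 500)
  expect_lt(autocorr_features(alt)["acf1"], -0.95)
  expect_true(all(is.na(autocorr_features(rep(1, 100)))))
})

test_that("tiled-window variances match the explicit tile-loop oracle", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(40:400, 1)
    w <- sample(5:30, 1)
    x <- rnorm(n)
    got <- window_variance_features(x, w)
    want <- oracle_tile_stats(x, w)
    expect_equal(unname(got), unname(want))
  }
  # permuting within tiles leaves tile statistics unchanged
  x <- rnorm(120)
  w <- 30
  perm <- as.vector(apply(matrix(seq_len(120), w), 2, sample))
  expect_equal(window_variance_features(x[perm], w),
               window_variance_features(x, w))
  expect_equal(unname(window_variance_features(rep(2, 100), 10)), c(0, 0))
  expect_true(all(is.na(window_variance_features(rnorm(15), 10))))
})

test_that("flat spots equal the brute-force run scan", {
  expect_identical(flat_spots(rep(7, 55)), 55L)
  expect_identical(flat_spots(0:99), 10L)
  expect_identical(flat_spots(c(rep(0, 50), 100, rep(0, 50))), 50L)
  set.seed(4)
  for (i in 1:100) {
    x <- sample(0:20, sample(10:200, 1), replace = TRUE)
    expect_identical(as.integer(flat_spots(x)), as.integer(oracle_flat_spots(x)))
  }
})

test_that("decomposition strengths respond to trend and seasonality", {
  set.seed(5)
  n <- 4320
  trend <- decomposition_features(seq_len(n) * 0.01 + rnorm(n, sd = 0.05), 1440)
  expect_gt(unname(trend["trend_strength"]), 0.9)
  noise <- decomposition_features(rnorm(n), 1440)
  expect_lt(unname(noise["trend_strength"]), 0.2)
  periodic <- decomposition_features(rep(sin(2 * pi * (1:1440) / 1440), 3), 1440)
  expect_gte(unname(periodic["seasonal_strength"]), 0.99)
  expect_true(all(is.na(decomposition_features(rnorm(1500), 1440))))
  # loess-based variant agrees qualitatively and records its method
  stl_res <- decomposition_features(seq_len(n) * 0.01 + rnorm(n, sd = 0.05),
                                    1440, method = "stl")
  expect_gt(unname(stl_res["trend_strength"]), 0.9)
  expect_identical(attr(stl_res, "method"), "stl")
})

test_that("Holt slope recovers linear trends", {
  f <- trend_features(3 * (1:200))
  expect_lt(abs(f["holt_slope"] - 3), 1e-3)
  f <- trend_features(rep(5, 100))
  expect_lt(abs(f["holt_slope"]), 1e-6)
  set.seed(6)
  signs <- vapply(1:60, function(i) {
    b <- sample(c(-2, 2), 1)
    sign(trend_features(b * (1:150) + rnorm(150, sd = 5))["holt_slope"]) == sign(b)
  }, logical(1))
  expect_true(all(signs))
})

test_that("Hurst and stationarity statistics separate noise from random walks", {
  set.seed(7)
  iid_h <- mean(vapply(1:20, function(i) {
    memory_stationarity_features(rnorm(4096))["hurst"]
  }, numeric(1)))
  expect_gt(iid_h, 0.4); expect_lt(iid_h, 0.6)
  rw_h <- vapply(1:10, function(i)
    memory_stationarity_features(cumsum(rnorm(4096)))["hurst"], numeric(1))
  expect_true(all(rw_h > 0.8))
  # KPSS rejects stationarity for random walks more than for noise
  paired <- vapply(1:60, function(i) {
    z <- rnorm(2048)
    k_rw <- memory_stationarity_features(cumsum(z))["kpss_level"]
    k_iid <- memory_stationarity_features(z)["kpss_level"]
    k_rw > k_iid
  }, logical(1))
  expect_gte(mean(paired), 0.95)
  expect_true(all(is.na(memory_stationarity_features(rep(1, 300)))))
})

test_that("the R/S Hurst estimate tracks an independent implementation", {
  set.seed(70)
  # the two R/S implementations average over different block-size grids, so
  # finite-sample estimates differ most for strongly autocorrelated series
  for (x in list(rnorm(2048), cumsum(rnorm(2048)),
                 as.numeric(arima.sim(list(ar = 0.9), 2048)))) {
    ours <- memory_stationarity_features(x)["hurst"]
    ref <- pracma::hurstexp(x, display = FALSE)$Hs
    expect_lt(abs(ours - min(max(ref, 0), 1)), 0.15)
  }
})

test_that("nonlinearity features show type-I control and detect quadratic maps", {
  set.seed(8)
  stats_lin <- vapply(1:100, function(i) {
    x <- as.numeric(arima.sim(list(ar = 0.5), 2000))
    nonlinearity_features(x)["terasvirta_stat"]
  }, numeric(1))
  reject <- mean(stats_lin > qchisq(0.95, df = 2))
  expect_lte(reject, 0.10)
  # bounded quadratic-lag map (noisy Henon, clamped): large R-squared gain
  set.seed(88)
  x <- numeric(2000); x[1:2] <- 0.1
  for (t in 3:2000)
    x[t] <- min(max(1 - 1.4 * x[t - 1]^2 + 0.3 * x[t - 2] +
                      rnorm(1, sd = 0.01), -2), 2)
  expect_gt(nonlinearity_features(x)["nonlinear_r2_gain"], 0.1)
  expect_true(all(is.na(nonlinearity_features(rep(2, 100)))))
})

test_that("heterogeneity features recover conditional heteroskedasticity", {
  set.seed(9)
  hom <- vapply(1:100, function(i)
    heterogeneity_features(rnorm(1024))["arch_lm"], numeric(1))
  expect_lte(mean(hom > qchisq(0.95, df = 12)), 0.10)
  sim_garch <- function(n, a = 0.2, b = 0.7, w = 0.1) {
    e <- numeric(n); h <- w / (1 - a - b); z <- rnorm(n)
    for (t in 1:n) { e[t] <- sqrt(h) * z[t]; h <- w + a * e[t]^2 + b * h }
    e
  }
  ab <- vapply(1:100, function(i)
    heterogeneity_features(sim_garch(4096))["garch_alpha_beta"], numeric(1))
  expect_gte(mean(ab >= 0.8 & ab <= 1.0, na.rm = TRUE), 0.8)
  expect_true(all(is.na(heterogeneity_features(rep(1, 512)))))
})

test_that("spectral band powers satisfy Parseval and localize tones", {
  set.seed(10)
  for (i in 1:20) {
    x <- rnorm(sample(64:2000, 1))
    p <- spectral_power_features(x)
    v <- mean((x - mean(x))^2)
    expect_lt(abs(sum(p) - v) / v, 1e-6)
  }
  # 2-hour-period sinusoid lands in the 1-8h band
  x <- sin(2 * pi * (1:2880) / 120)
  p <- spectral_power_features(x)
  expect_gt(p["power_mid"] / sum(p), 0.95)
  # white noise spreads power roughly proportional to band width
  x <- rnorm(100000)
  p <- spectral_power_features(x)
  widths <- diff(1 / c(Inf, 480, 60, 1))
  expect_equal(unname(p / sum(p)), widths / sum(widths), tolerance = 0.05)
})

test_that("features scale as documented under multiplicative rescaling", {
  set.seed(71)
  x <- abs(rnorm(1024)) * 100
  c_ <- 3.7
  # scale-invariant features
  expect_equal(entropy_features(c_ * x)["spectral_entropy"],
               entropy_features(x)["spectral_entropy"])
  expect_equal(autocorr_features(c_ * x)["acf1"], autocorr_features(x)["acf1"])
  expect_equal(memory_stationarity_features(c_ * x)["hurst"],
               memory_stationarity_features(x)["hurst"], tolerance = 1e-8)
  expect_identical(flat_spots(c_ * x), flat_spots(x))
  # linearly / quadratically scaling features
  d1 <- distributional_features(x); d2 <- distributional_features(c_ * x)
  expect_equal(unname(d2["sd"]), c_ * unname(d1["sd"]))
  expect_equal(unname(d2["rmssd"]), c_ * unname(d1["rmssd"]))
  w1 <- window_variance_features(x); w2 <- window_variance_features(c_ * x)
  expect_equal(unname(w2["stability"]), c_^2 * unname(w1["stability"]))
  expect_equal(unname(w2["lumpiness"]), c_^4 * unname(w1["lumpiness"]))
  p1 <- spectral_power_features(x); p2 <- spectral_power_features(c_ * x)
  expect_equal(unname(p2), c_^2 * unname(p1))
})

test_that("feature extraction respects the catalog contract", {
  coh <- small_cohort(n = 60)
  masks <- lapply(coh$series, detect_nonwear)
  filt <- compliance_filter(masks)
  sid <- filt$included[1]
  cat_dist <- feature_catalog("distributional")
  fv <- extract_subject_features(coh$series[[sid]], masks[[sid]], cat_dist)
  expect_identical(names(fv), cat_dist$name)
  expect_true(all(startsWith(names(fv), "distributional.")))
  # identical days collapse every across-day SD to zero
  day <- integer(1440)
  day[481:1380] <- 150L + (seq_len(900) %% 60L) * 5L
  rep_series <- epoch_series("const", rep(day, 7))
  m <- detect_nonwear(rep_series)
  fv7 <- extract_subject_features(rep_series, m)
  sds <- fv7[grepl("\\.sd$", names(fv7))]
  expect_true(all(abs(sds[!is.na(sds)]) < 1e-12))
  # subjects with no valid day are an error, not a silent NA row
  empty <- epoch_series("none", integer(10080))
  expect_error(extract_subject_features(empty, detect_nonwear(empty)),
               "no valid day")
})

test_that("the feature matrix is invariant to subject processing order", {
  coh <- small_cohort(n = 60)
  masks <- lapply(coh$series, detect_nonwear)
  ids <- compliance_filter(masks)$included[1:4]
  fwd <- build_feature_matrix(coh$series, masks, subject_ids = ids)
  rev_ <- build_feature_matrix(coh$series, masks, subject_ids = rev(ids))
  rev_ <- rev_[match(ids, rev_$subject_id), ]
  rownames(rev_) <- NULL
  expect_equal(fwd, rev_)
})

test_that("feature matrix round-trips through CSV with sidecar", {
  coh <- small_cohort(n = 60)
  masks <- lapply(coh$series, detect_nonwear)
  ids <- compliance_filter(masks)$included[1:3]
  fm <- build_feature_matrix(coh$series, masks, subject_ids = ids)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, path, meta = list(gap_policy = "concatenate"))
  back <- read_feature_matrix(path)
  expect_equal(as.data.frame(fm), as.data.frame(back), tolerance = 1e-12)
  expect_true(file.exists(paste0(path, ".meta.json")))
})

test_that("movement coupling leaves a detectable feature signal", {
  coh <- small_cohort(n = 60)
  masks <- lapply(coh$series, detect_nonwear)
  ids <- compliance_filter(masks)$included
  fm <- build_feature_matrix(coh$series, masks, subject_ids = ids)
  th <- coh$latent$theta_gad[match(ids, coh$latent$subject_id)]
  cors <- vapply(fm[, setdiff(names(fm), c("subject_id", "n_valid_days"))],
                 function(v) if (stats::sd(v, na.rm = TRUE) > 0)
                   abs(cor(v, th, use = "complete.obs")) else 0, numeric(1))
  expect_gt(max(cors), 0.2)
})
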