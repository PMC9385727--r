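# Per-subject time-series feature catalog computed on wear-masked minute
# counts. Day-level features are computed on each valid day's wear-only
# minutes and aggregated across days by mean and SD; week-level features
# (wear-time totals/bouts and period-1440 decomposition strengths) are
# computed once per subject.

#' Distributional features
#'
#' Mean, sample SD, skewness, kurtosis, root mean square of successive
#' differences, and the 10th/30th/70th/90th quantiles (linear-interpolation
#' convention, i.e. type 7).
#'
#' @param x numeric vector.
#' @return named numeric vector; with fewer than 2 values everything but the
#'   mean is missing.
#' @export
distributional_features <- function(x) {
  out <- c(mean = NA_real_, sd = NA_real_, skewness = NA_real_,
           kurtosis = NA_real_, rmssd = NA_real_,
           q10 = NA_real_, q30 = NA_real_, q70 = NA_real_, q90 = NA_real_)
  x <- x[is.finite(x)]
  if (length(x) == 0) return(out)
  out["mean"] <- mean(x)
  if (length(x) < 2) return(out)
  out["sd"] <- stats::sd(x)
  out["skewness"] <- e1071::skewness(x, type = 1)
  out["kurtosis"] <- e1071::kurtosis(x, type = 1)
  out["rmssd"] <- sqrt(mean(diff(x)^2))
  q <- stats::quantile(x, c(0.1, 0.3, 0.7, 0.9), type = 7, names = FALSE)
  out[c("q10", "q30", "q70", "q90")] <- q
  out
}

#' Entropy features
#'
#' Spectral entropy is the Shannon entropy of the normalized periodogram
#' divided by the log of the number of frequencies (so it lies in \[0, 1\];
#' near 0 for a pure tone, near 1 for white noise). Binary entropy is the
#' natural-log Shannon entropy of the proportion of values above the series
#' mean (0 for a constant series).
#'
#' @param x numeric vector.
#' @return named numeric vector `spectral_entropy`, `binary_entropy`.
#' @export
entropy_features <- function(x) {
  out <- c(spectral_entropy = NA_real_, binary_entropy = NA_real_)
  n <- length(x)
  if (n < 2) return(out)
  p_above <- mean(x > mean(x))
  out["binary_entropy"] <- if (p_above %in% c(0, 1)) 0 else
    -p_above * log(p_above) - (1 - p_above) * log(1 - p_above)
  if (n >= 16 && stats::sd(x) > 0) {
    spec <- periodogram(x)
    p <- spec$power / sum(spec$power)
    p <- p[p > 0]
    out["spectral_entropy"] <- -sum(p * log(p)) / log(length(spec$power))
  }
  out
}

# one-sided periodogram (DC excluded); powers sum to the population variance
periodogram <- function(x) {
  n <- length(x)
  z <- stats::fft(x - mean(x))
  m <- n %/% 2
  power <- (Mod(z[2:(m + 1)])^2) / n^2
  # fold in the conjugate half; Nyquist bin (even n) has no mirror
  mult <- rep(2, m)
  if (n %% 2 == 0) mult[m] <- 1
  list(freq = (1:m) / n, power = power * mult)
}

#' Autocorrelation features
#'
#' ACF at lags 1-3, sum of squared ACF over the first 10 lags, and the lag of
#' the first zero crossing of the ACF.
#'
#' @param x numeric vector.
#' @param max_lag maximum lag (default 10).
#' @return named numeric vector; missing for constant series.
#' @export
autocorr_features <- function(x, max_lag = 10) {
  out <- c(acf1 = NA_real_, acf2 = NA_real_, acf3 = NA_real_,
           sumsq10 = NA_real_, first_zero = NA_real_)
  if (length(x) <= max_lag || stats::sd(x) == 0) return(out)
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1]
  out["acf1"] <- a[1]; out["acf2"] <- a[2]; out["acf3"] <- a[3]
  out["sumsq10"] <- sum(a[seq_len(min(10, length(a)))]^2)
  z <- which(a <= 0)
  out["first_zero"] <- if (length(z)) z[1] else max_lag + 1
  out
}

#' Tiled-window variance features
#'
#' Stability is the variance of the means of non-overlapping tiles;
#' lumpiness is the variance of the tile variances. The incomplete trailing
#' tile is dropped.
#'
#' @param x numeric vector.
#' @param tile_width tile width in observations (default 60).
#' @return named numeric vector `stability`, `lumpiness`; missing with fewer
#'   than 2 complete tiles.
#' @export
window_variance_features <- function(x, tile_width = 60) {
  k <- length(x) %/% tile_width
  if (k < 2) return(c(stability = NA_real_, lumpiness = NA_real_))
  m <- matrix(x[seq_len(k * tile_width)], nrow = tile_width)
  c(stability = stats::var(colMeans(m)),
    lumpiness = stats::var(apply(m, 2, stats::var)))
}

#' Flat spots
#'
#' Discretizes the series into 10 equal-width bins over its range and returns
#' the length of the longest run of identical bin labels. A constant series
#' occupies a single bin, so the whole length is returned.
#'
#' @param x numeric vector.
#' @return integer run length (NA if fewer than 10 observations).
#' @export
flat_spots <- function(x) {
  n <- length(x)
  if (n < 10) return(NA_integer_)
  rng <- range(x)
  if (rng[1] == rng[2]) return(n)
  breaks <- seq(rng[1], rng[2], length.out = 11)
  bins <- .bincode(x, breaks, right = TRUE, include.lowest = TRUE)
  max(rle(bins)$lengths)
}

#' Seasonal-trend decomposition strengths
#'
#' Decomposes the series at the given period (moving-average seasonal-trend
#' decomposition via [stats::decompose()]; a loess variant via [stats::stl()]
#' is selectable) and returns trend strength
#' `max(0, 1 - Var(remainder) / Var(trend + remainder))` and seasonal
#' strength `max(0, 1 - Var(remainder) / Var(seasonal + remainder))`.
#'
#' @param x numeric vector.
#' @param period seasonal period (default 1440, one day of minutes).
#' @param method `"ma"` (default, moving average) or `"stl"` (loess).
#' @return named numeric vector `trend_strength`, `seasonal_strength`, with a
#'   `method` attribute recording the decomposition used.
#' @export
decomposition_features <- function(x, period = 1440, method = c("ma", "stl")) {
  method <- match.arg(method)
  out <- c(trend_strength = NA_real_, seasonal_strength = NA_real_)
  if (length(x) < 2 * period || stats::sd(x) == 0) {
    attr(out, "method") <- method
    return(out)
  }
  xt <- stats::ts(x, frequency = period)
  dec <- tryCatch(
    if (method == "ma") {
      ma_decompose(x, period)
    } else {
      d <- stats::stl(xt, s.window = "periodic")
      list(trend = as.numeric(d$time.series[, "trend"]),
           seasonal = as.numeric(d$time.series[, "seasonal"]),
           remainder = as.numeric(d$time.series[, "remainder"]))
    }, error = function(e) NULL)
  if (!is.null(dec)) {
    ok <- is.finite(dec$remainder) & is.finite(dec$trend)
    vr <- stats::var(dec$remainder[ok])
    vtr <- stats::var((dec$trend + dec$remainder)[ok])
    vsr <- stats::var((dec$seasonal + dec$remainder)[ok])
    if (isTRUE(vtr > 0)) out["trend_strength"] <- max(0, 1 - vr / vtr)
    if (isTRUE(vsr > 0)) out["seasonal_strength"] <- max(0, 1 - vr / vsr)
  }
  attr(out, "method") <- method
  out
}

# classical additive moving-average seasonal-trend decomposition, O(n) via
# cumulative sums (numerically equivalent to stats::decompose)
ma_decompose <- function(x, period) {
  n <- length(x)
  p <- period
  cs <- c(0, cumsum(x))
  roll <- function(i) (cs[i + p + 1] - cs[i + 1]) / p  # mean of x[(i+1):(i+p)]
  trend <- rep(NA_real_, n)
  if (p %% 2 == 0) {
    h <- p %/% 2
    t_idx <- (h + 1):(n - h)
    trend[t_idx] <- (roll(t_idx - h - 1) + roll(t_idx - h)) / 2
  } else {
    h <- (p - 1) %/% 2
    t_idx <- (h + 1):(n - h)
    trend[t_idx] <- roll(t_idx - h - 1)
  }
  detr <- x - trend
  cyc <- rep_len(seq_len(p), n)
  figure <- vapply(split(detr, cyc), mean, numeric(1), na.rm = TRUE)
  figure <- figure - mean(figure)
  seasonal <- figure[cyc]
  list(trend = trend, seasonal = seasonal, remainder = x - seasonal - trend)
}

#' Holt linear-trend features
#'
#' Fits Holt's additive level-plus-trend exponential smoothing (squared-error
#' minimization over the smoothing parameters) and returns the final smoothed
#' slope and the fitted smoothing parameters.
#'
#' @param x numeric vector (length at least 10).
#' @return named numeric vector `holt_slope`, `holt_alpha`, `holt_beta`.
#' @export
trend_features <- function(x) {
  out <- c(holt_slope = NA_real_, holt_beta = NA_real_, holt_alpha = NA_real_)
  if (length(x) < 10) return(out)
  fit <- tryCatch(
    suppressWarnings(stats::HoltWinters(stats::ts(x), gamma = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  out["holt_slope"] <- unname(fit$coefficients["b"])
  out["holt_alpha"] <- unname(fit$alpha)
  out["holt_beta"] <- unname(fit$beta)
  out
}

#' Long-range memory and stationarity features
#'
#' Hurst exponent by the rescaled-range (R/S) estimator (log-log regression
#' of the block-averaged R/S statistic on block size, clamped to \[0, 1\]),
#' the KPSS level statistic (Bartlett long-run variance, lag
#' `trunc(4 * (n/100)^0.25)`), and the augmented Dickey-Fuller t statistic
#' (intercept, `trunc((n-1)^(1/3))` lagged differences).
#'
#' @param x numeric vector (Hurst requires length >= 128).
#' @return named numeric vector `hurst`, `kpss_level`, `adf_stat`; missing
#'   for constant series.
#' @export
memory_stationarity_features <- function(x) {
  out <- c(hurst = NA_real_, kpss_level = NA_real_, adf_stat = NA_real_)
  if (!all(is.finite(x)) || length(x) < 16 || stats::sd(x) == 0) return(out)
  out["hurst"] <- hurst_rs(x)
  out["kpss_level"] <- kpss_level(x)
  out["adf_stat"] <- adf_stat(x)
  out
}

# rescaled-range Hurst estimate
hurst_rs <- function(x) {
  n <- length(x)
  if (n < 128 || stats::sd(x) == 0) return(NA_real_)
  sizes <- unique(floor(n / 2^(0:20)))
  sizes <- sizes[sizes >= 16]
  rs <- numeric(0); ms <- numeric(0)
  for (m in sizes) {
    k <- n %/% m
    blocks <- matrix(x[seq_len(k * m)], nrow = m)
    dev <- sweep(blocks, 2, colMeans(blocks))
    cs <- apply(dev, 2, cumsum)
    if (k == 1) cs <- matrix(cs, ncol = 1)
    R <- apply(cs, 2, max) - apply(cs, 2, min)
    S <- sqrt(colMeans(dev^2))
    ok <- S > 0
    if (any(ok)) { rs <- c(rs, mean(R[ok] / S[ok])); ms <- c(ms, m) }
  }
  if (length(ms) < 3) return(NA_real_)
  h <- unname(stats::coef(stats::lm(log(rs) ~ log(ms)))[2])
  min(max(h, 0), 1)
}

kpss_level <- function(x) {
  n <- length(x)
  e <- x - mean(x)
  s <- cumsum(e)
  l <- trunc(4 * (n / 100)^0.25)
  g0 <- mean(e^2)
  lrv <- g0
  if (l >= 1) for (j in seq_len(l))
    lrv <- lrv + 2 * (1 - j / (l + 1)) * mean(e[1:(n - j)] * e[(j + 1):n])
  if (lrv <= 0) return(NA_real_)
  sum(s^2) / (n^2 * lrv)
}

adf_stat <- function(x) {
  n <- length(x)
  k <- trunc((n - 1)^(1 / 3))
  dx <- diff(x)
  m <- length(dx)
  if (m <= k + 2) return(NA_real_)
  y <- dx[(k + 1):m]
  X <- cbind(1, x[(k + 1):m])
  if (k >= 1) for (i in seq_len(k)) X <- cbind(X, dx[(k + 1 - i):(m - i)])
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  df <- length(y) - ncol(X)
  if (df <= 0) return(NA_real_)
  sigma2 <- sum(res^2) / df
  xtxinv <- tryCatch(chol2inv(chol(crossprod(X))), error = function(e) NULL)
  if (is.null(xtxinv)) return(NA_real_)
  se <- sqrt(sigma2 * xtxinv[2, 2])
  unname(fit$coefficients[2] / se)
}

#' Nonlinearity features
#'
#' The Terasvirta neural-network-type test statistic (chi-squared form:
#' `n * R^2` of regressing the linear-AR(1) residuals on quadratic and cubic
#' Volterra terms of the lagged series) and the nonlinear-lag feature, the
#' R-squared gain of regressing `x_t` on `x_{t-1}, x_{t-1}^2, x_{t-1}^3`
#' over `x_{t-1}` alone.
#'
#' @param x numeric vector (length >= 64).
#' @return named numeric vector `terasvirta_stat`, `nonlinear_r2_gain`;
#'   missing when the regressors are degenerate. The statistic is
#'   asymptotically chi-squared with 2 degrees of freedom under linearity.
#' @export
nonlinearity_features <- function(x) {
  out <- c(terasvirta_stat = NA_real_, nonlinear_r2_gain = NA_real_)
  n <- length(x)
  if (!all(is.finite(x)) || n < 64 || stats::sd(x) == 0) return(out)
  z <- as.numeric(scale(x))
  y <- z[-1]; y1 <- z[-n]
  if (stats::sd(y1) == 0) return(out)
  m <- length(y)
  lin <- stats::lm.fit(cbind(1, y1), y)
  e <- lin$residuals
  sse0 <- sum(e^2)
  if (sse0 <= 0) return(out)
  aux <- stats::lm.fit(cbind(1, y1, y1^2, y1^3), e)
  r2aux <- 1 - sum(aux$residuals^2) / sum((e - mean(e))^2)
  out["terasvirta_stat"] <- m * max(0, r2aux)
  cube <- stats::lm.fit(cbind(1, y1, y1^2, y1^3), y)
  tss <- sum((y - mean(y))^2)
  r2_lin <- 1 - sse0 / tss
  r2_cube <- 1 - sum(cube$residuals^2) / tss
  out["nonlinear_r2_gain"] <- max(0, r2_cube - r2_lin)
  out
}

#' Conditional-heteroskedasticity features
#'
#' The series is prewhitened by removing the mean, a linear trend, and an
#' AR(p) fit (AIC-selected, p <= 5). On the residuals it computes (i) the
#' ARCH-LM statistic (`n * R^2` of regressing squared residuals on their
#' first 12 lags) and (ii) the fitted `alpha + beta` of a Gaussian GARCH(1,1)
#' maximum-likelihood fit (variance-targeted, Nelder-Mead). If the GARCH fit
#' fails, the ARCH-LM statistic is still returned.
#'
#' @param x numeric vector (length >= 256 recommended).
#' @param arch_lags lags of the ARCH-LM regression (default 12).
#' @return named numeric vector `arch_lm`, `garch_alpha_beta`.
#' @export
heterogeneity_features <- function(x, arch_lags = 12) {
  out <- c(arch_lm = NA_real_, garch_alpha_beta = NA_real_)
  n <- length(x)
  if (!all(is.finite(x)) || n < 64 || stats::sd(x) == 0) return(out)
  t <- seq_len(n)
  detr <- stats::lm.fit(cbind(1, t), x)$residuals
  arfit <- tryCatch(stats::ar(detr, order.max = 5, aic = TRUE, method = "yule-walker"),
                    error = function(e) NULL)
  e <- if (!is.null(arfit)) stats::na.omit(arfit$resid) else detr
  e <- as.numeric(e)
  if (length(e) < arch_lags + 8 || stats::sd(e) == 0) return(out)
  out["arch_lm"] <- arch_lm_stat(e, arch_lags)
  g <- garch11_fit(e)
  if (all(is.finite(g))) out["garch_alpha_beta"] <- g["alpha"] + g["beta"]
  out
}

arch_lm_stat <- function(e, lags = 12) {
  e2 <- e^2
  m <- length(e2) - lags
  y <- e2[(lags + 1):length(e2)]
  X <- cbind(1, sapply(seq_len(lags), function(i) e2[(lags + 1 - i):(length(e2) - i)]))
  fit <- stats::lm.fit(X, y)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) return(NA_real_)
  r2 <- 1 - sum(fit$residuals^2) / tss
  m * max(0, r2)
}

# Gaussian GARCH(1,1) MLE with variance targeting; returns c(alpha, beta)
garch11_fit <- function(e) {
  e <- e[is.finite(e)]
  n <- length(e)
  v <- stats::var(e)
  if (!is.finite(v) || v <= 0 || n < 128) return(c(alpha = NA_real_, beta = NA_real_))
  e2 <- e^2
  negll <- function(p) {
    a <- stats::plogis(p[1]) * 0.999
    b <- stats::plogis(p[2]) * (0.999 - a)
    w <- v * (1 - a - b)
    h <- stats::filter(w + a * c(v, e2[-n]), b, method = "recursive", init = v)
    h <- pmax(as.numeric(h), 1e-12)
    0.5 * sum(log(h) + e2 / h)
  }
  fit <- tryCatch(stats::optim(c(stats::qlogis(0.1), stats::qlogis(0.8 / 0.9)),
                               negll, method = "Nelder-Mead",
                               control = list(maxit = 500)),
                  error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) return(c(alpha = NA_real_, beta = NA_real_))
  a <- stats::plogis(fit$par[1]) * 0.999
  b <- stats::plogis(fit$par[2]) * (0.999 - a)
  c(alpha = a, beta = b)
}

#' Spectral band-power features
#'
#' Periodogram power aggregated into three frequency bands, by default
#' periods above 8 hours, 1-8 hours, and below 1 hour for minute-epoch data.
#' Band powers sum to the series (population) variance by Parseval's
#' identity.
#'
#' @param x numeric vector (length >= 64).
#' @param band_periods band edges as periods in observations, descending
#'   (default `c(Inf, 480, 60, 1)`).
#' @return named numeric vector `power_low`, `power_mid`, `power_high`.
#' @export
spectral_power_features <- function(x, band_periods = c(Inf, 480, 60, 1)) {
  out <- c(power_low = NA_real_, power_mid = NA_real_, power_high = NA_real_)
  if (length(x) < 64) return(out)
  if (stats::sd(x) == 0) return(c(power_low = 0, power_mid = 0, power_high = 0))
  spec <- periodogram(x)
  edges <- 1 / band_periods  # ascending frequencies
  band <- cut(spec$freq, breaks = edges, include.lowest = TRUE, labels = FALSE)
  for (i in 1:3) out[i] <- sum(spec$power[which(band == i)])
  out
}

#' Feature catalog
#'
#' Enumerates the features the extractor computes, grouped into families:
#' day-level features (computed per valid day on wear-only minutes, then
#' aggregated across days by mean and SD) and week-level features (wear-time
#' totals and bouts, decomposition strengths at period 1440).
#'
#' @param families optional subset of family names to keep.
#' @return data.frame with columns `name`, `family`, `level`.
#' @export
feature_catalog <- function(families = NULL) {
  day <- c(
    stats::setNames(rep("distributional", 9),
             paste0("distributional.", c("mean", "sd", "skewness", "kurtosis",
                                         "rmssd", "q10", "q30", "q70", "q90"))),
    stats::setNames(rep("entropy", 2), paste0("entropy.", c("spectral_entropy", "binary_entropy"))),
    stats::setNames(rep("autocorrelation", 5),
             paste0("autocorrelation.", c("acf1", "acf2", "acf3", "sumsq10", "first_zero"))),
    stats::setNames(rep("window_variance", 2), paste0("window_variance.", c("stability", "lumpiness"))),
    stats::setNames("flatspots", "flatspots.flat_spots"),
    stats::setNames(rep("memory", 1), "memory.hurst"),
    stats::setNames(rep("stationarity", 2), paste0("stationarity.", c("kpss_level", "adf_stat"))),
    stats::setNames(rep("nonlinearity", 2),
             paste0("nonlinearity.", c("terasvirta_stat", "nonlinear_r2_gain"))),
    stats::setNames(rep("heterogeneity", 2), paste0("heterogeneity.", c("arch_lm", "garch_alpha_beta"))),
    stats::setNames(rep("trend", 3), paste0("trend.", c("holt_slope", "holt_beta", "holt_alpha"))),
    stats::setNames(rep("spectral", 3), paste0("spectral.", c("power_low", "power_mid", "power_high")))
  )
  day_tab <- data.frame(
    name = as.vector(outer(names(day), c("mean", "sd"), paste, sep = ".")),
    family = rep(unname(day), 2), level = "day", stringsAsFactors = FALSE)
  week_tab <- data.frame(
    name = c("weartime.total_minutes", "weartime.n_bouts", "weartime.mean_bout",
             "weartime.max_bout", "weartime.n_valid_days",
             "decomposition.trend_strength", "decomposition.seasonal_strength"),
    family = c(rep("weartime", 5), rep("decomposition", 2)),
    level = "week", stringsAsFactors = FALSE)
  cat_tab <- rbind(day_tab, week_tab)
  if (!is.null(families)) cat_tab <- cat_tab[cat_tab$family %in% families, , drop = FALSE]
  cat_tab
}

# the 32 day-level raw features, in catalog order, family-prefixed
compute_day_features <- function(x) {
  pre <- function(fam, v) stats::setNames(v, paste0(fam, ".", names(v)))
  ms <- memory_stationarity_features(x)
  c(pre("distributional", distributional_features(x)),
    pre("entropy", entropy_features(x)),
    pre("autocorrelation", autocorr_features(x)),
    pre("window_variance", window_variance_features(x)),
    "flatspots.flat_spots" = as.numeric(flat_spots(x)),
    "memory.hurst" = unname(ms["hurst"]),
    "stationarity.kpss_level" = unname(ms["kpss_level"]),
    "stationarity.adf_stat" = unname(ms["adf_stat"]),
    pre("nonlinearity", nonlinearity_features(x)),
    pre("heterogeneity", heterogeneity_features(x)),
    pre("trend", trend_features(x)[c("holt_slope", "holt_beta", "holt_alpha")]),
    pre("spectral", spectral_power_features(x)))
}

#' Extract one subject's feature vector
#'
#' Splits the recording into days; a day is valid when it has at least
#' `valid_day_minutes` of wear. Day-level features are computed on the day's
#' wear-only minutes (non-wear gaps closed by concatenation, the default, or
#' kept as zeros) and aggregated across valid days by mean and SD. Week-level
#' features are the wear-time summary, the number of valid days, and the
#' period-1440 decomposition strengths of the full count series.
#'
#' @param series an [epoch_series()].
#' @param mask matching `wear_mask`.
#' @param catalog a [feature_catalog()] (used to subset/order the output).
#' @param valid_day_minutes minimum wear minutes for a valid day (default 600).
#' @param gap_policy `"concatenate"` (default) or `"zero_fill"`.
#' @param decomposition_method passed to [decomposition_features()].
#' @return named numeric vector over `catalog$name` plus attribute
#'   `n_valid_days`; errors if the subject has no valid day.
#' @export
extract_subject_features <- function(series, mask, catalog = feature_catalog(),
                                     valid_day_minutes = 600,
                                     gap_policy = c("concatenate", "zero_fill"),
                                     decomposition_method = "ma") {
  gap_policy <- match.arg(gap_policy)
  nd <- series$n_days
  day_feats <- list()
  n_valid <- 0L
  for (d in seq_len(nd)) {
    idx <- ((d - 1L) * 1440L + 1L):(d * 1440L)
    w <- mask$wear[idx]
    if (sum(w) < valid_day_minutes) next
    x <- if (gap_policy == "concatenate") as.numeric(series$counts[idx][w])
         else as.numeric(series$counts[idx])
    n_valid <- n_valid + 1L
    day_feats[[n_valid]] <- compute_day_features(x)
  }
  if (n_valid == 0L)
    stopf("extract_subject_features: subject %s has no valid day (should have been filtered)",
          series$subject_id)
  fm <- do.call(rbind, day_feats)
  agg_mean <- colMeans(fm, na.rm = TRUE)
  agg_sd <- apply(fm, 2, stats::sd, na.rm = TRUE)
  agg_mean[!is.finite(agg_mean)] <- NA_real_
  agg_sd[!is.finite(agg_sd)] <- NA_real_
  day_vec <- c(stats::setNames(agg_mean, paste0(colnames(fm), ".mean")),
               stats::setNames(agg_sd, paste0(colnames(fm), ".sd")))
  ws <- weartime_summary(mask)
  dec <- decomposition_features(as.numeric(series$counts), period = 1440,
                                method = decomposition_method)
  week_vec <- c("weartime.total_minutes" = ws$total_wear_minutes,
                "weartime.n_bouts" = ws$n_bouts,
                "weartime.mean_bout" = ws$mean_bout_length,
                "weartime.max_bout" = ws$max_bout_length,
                "weartime.n_valid_days" = as.numeric(n_valid),
                "decomposition.trend_strength" = unname(dec["trend_strength"]),
                "decomposition.seasonal_strength" = unname(dec["seasonal_strength"]))
  full <- c(day_vec, week_vec)
  out <- full[catalog$name]
  names(out) <- catalog$name
  attr(out, "n_valid_days") <- n_valid
  out
}

#' Build the cohort feature matrix
#'
#' @param series_list named list of [epoch_series()].
#' @param masks matching named list of wear masks.
#' @param subject_ids subjects to include (default: all of `series_list`).
#' @param catalog a [feature_catalog()].
#' @param ... passed to [extract_subject_features()].
#' @return data.frame: `subject_id`, `n_valid_days`, then one column per
#'   catalog feature (NA marks an explicitly missing value).
#' @export
build_feature_matrix <- function(series_list, masks,
                                 subject_ids = names(series_list),
                                 catalog = feature_catalog(), ...) {
  rows <- lapply(subject_ids, function(sid) {
    fv <- extract_subject_features(series_list[[sid]], masks[[sid]], catalog, ...)
    c(n_valid_days = attr(fv, "n_valid_days"), fv)
  })
  m <- do.call(rbind, rows)
  out <- data.frame(subject_id = subject_ids, m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read a feature matrix with its metadata sidecar
#'
#' The CSV holds one row per subject; the JSON sidecar records the catalog
#' and the extraction parameters actually used.
#'
#' @param features feature matrix data.frame.
#' @param path CSV path (sidecar written alongside as `<path>.meta.json`).
#' @param meta named list of extraction metadata.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path, meta = list()) {
  data.table::fwrite(features, path)
  jsonlite::write_json(list(features = setdiff(names(features), "subject_id"),
                            meta = meta),
                       paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  as.data.frame(data.table::fread(path, colClasses = list(character = "subject_id")),
                check.names = FALSE)
}
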