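# Brute-force oracles, kept deliberately naive and independent of the
# package implementations they check.

# a minute is non-wear iff it lies in ANY window of length >= minw whose
# counts are all < ceiling with at most `allow` nonzero minutes
oracle_nonwear <- function(x, minw = 60, allow = 2, ceiling = 100) {
  n <- length(x)
  nonwear <- logical(n)
  big <- cumsum(x >= ceiling)
  spk <- cumsum(x > 0 & x < ceiling)
  for (i in seq_len(n)) {
    js <- i:n
    ok <- (big[js] - big[i] + (x[i] >= ceiling)) == 0 &
      (spk[js] - spk[i] + (x[i] > 0 & x[i] < ceiling)) <= allow &
      (js - i + 1) >= minw
    if (any(ok)) {
      j <- max(js[ok])
      nonwear[i:j] <- TRUE
    }
  }
  nonwear
}

oracle_flat_spots <- function(x) {
  if (length(x) < 10) return(NA_integer_)
  if (min(x) == max(x)) return(length(x))
  b <- cut(x, breaks = seq(min(x), max(x), length.out = 11),
           include.lowest = TRUE, labels = FALSE)
  best <- 1L; run <- 1L
  for (i in seq_along(b)[-1]) {
    run <- if (b[i] == b[i - 1]) run + 1L else 1L
    best <- max(best, run)
  }
  best
}

oracle_tile_stats <- function(x, w) {
  k <- length(x) %/% w
  if (k < 2) return(c(stability = NA_real_, lumpiness = NA_real_))
  means <- vars <- numeric(k)
  for (i in seq_len(k)) {
    tile <- x[((i - 1) * w + 1):(i * w)]
    means[i] <- sum(tile) / w
    vars[i] <- sum((tile - means[i])^2) / (w - 1)
  }
  c(stability = sum((means - mean(means))^2) / (k - 1),
    lumpiness = sum((vars - mean(vars))^2) / (k - 1))
}

oracle_rmssd <- function(x) {
  d <- x[-1] - x[-length(x)]
  sqrt(sum(d^2) / length(d))
}

# linear-interpolation quantile between order statistics
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[pmin(lo + 2, length(x))] - s[lo + 1])
}

oracle_binary_entropy <- function(x) {
  p <- sum(x > mean(x)) / length(x)
  if (p == 0 || p == 1) return(0)
  -p * log(p) - (1 - p) * log(1 - p)
}

# trapezoidal AUC over the ROC curve, in (1 - specificity, sensitivity) space
oracle_trapezoid_auc <- function(roc) {
  fpr <- 1 - roc$specificity
  o <- order(fpr, roc$sensitivity)
  fpr <- fpr[o]; sens <- roc$sensitivity[o]
  sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
}

# random count-like series mixing zeros, sub-ceiling and large values
random_count_series <- function(n, p_zero = 0.6, p_spike = 0.2) {
  u <- stats::runif(n)
  ifelse(u < p_zero, 0L,
         ifelse(u < p_zero + p_spike, sample.int(99, n, replace = TRUE),
                100L + sample.int(900, n, replace = TRUE)))
}

# tiny deterministic cohort shared across tests (cached per session)
small_cohort <- local({
  cache <- NULL
  function(n = 60, seed = 42, ...) {
    key <- paste(n, seed, ...)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$value)
    value <- generate_cohort(cohort_config(n_subjects = n, seed = seed, ...))
    cache <<- list(key = key, value = value)
    value
  }
})

# synthetic feature matrix + targets for ensemble tests (no actigraphy)
synth_features <- function(n, p, seed, planted = FALSE, noise_sd = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(sprintf("S%04d", seq_len(n)),
                              sprintf("f%03d", seq_len(p))))
  y <- stats::rnorm(n)
  if (planted) X[, 1] <- y + stats::rnorm(n, sd = noise_sd)
  list(X = X, y = stats::setNames(y, rownames(X)))
}
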