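# Minute-epoch actigraphy containers, CSV I/O, non-wear detection and the
# half-week compliance filter.

#' Minute-epoch activity count series
#'
#' @param subject_id identifier.
#' @param counts non-negative integer counts, length a multiple of 1440
#'   (one-minute epochs).
#' @return object of class `epoch_series` with fields `subject_id`, `n_days`,
#'   `counts`, `epoch_seconds` (always 60).
#' @export
epoch_series <- function(subject_id, counts) {
  counts <- as.integer(counts)
  if (length(counts) == 0 || length(counts) %% 1440L != 0L)
    stopf("epoch_series: counts length must be a positive multiple of 1440")
  if (anyNA(counts) || any(counts < 0L))
    stopf("epoch_series: counts must be non-negative integers")
  structure(list(subject_id = as.character(subject_id),
                 n_days = length(counts) %/% 1440L,
                 counts = counts, epoch_seconds = 60L),
            class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> subject %s: %d days, %d minutes, mean count %.1f\n",
              x$subject_id, x$n_days, length(x$counts), mean(x$counts)))
  invisible(x)
}

#' Write epoch series to CSV
#'
#' Long format, one row per subject-minute with 1-based `day` and `minute`
#' columns: `subject_id,day,minute,counts`.
#'
#' @param series_list list of [epoch_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_epoch_table <- function(series_list, path) {
  tabs <- lapply(series_list, function(s) {
    data.table::data.table(
      subject_id = s$subject_id,
      day = rep(seq_len(s$n_days), each = 1440L),
      minute = rep(1:1440, times = s$n_days),
      counts = s$counts)
  })
  data.table::fwrite(data.table::rbindlist(tabs), path)
  invisible(path)
}

#' Read epoch series from CSV
#'
#' Expects columns `subject_id, day, minute, counts` with 1-based day and
#' minute-of-day. Missing minutes are zero-filled with a warning (a device
#' returning no signal), negative counts and duplicate (subject, day, minute)
#' rows are validation errors.
#'
#' @param path CSV path.
#' @return named list of [epoch_series()].
#' @export
read_epoch_table <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "subject_id"))
  need <- c("subject_id", "day", "minute", "counts")
  if (!all(need %in% names(dt)))
    stopf("read_epoch_table: missing columns %s",
          paste(setdiff(need, names(dt)), collapse = ", "))
  bad <- which(dt$counts < 0)
  if (length(bad))
    stopf("read_epoch_table: negative count at row %d (subject %s, day %d, minute %d)",
          bad[1], dt$subject_id[bad[1]], dt$day[bad[1]], dt$minute[bad[1]])
  if (any(dt$minute < 1 | dt$minute > 1440))
    stopf("read_epoch_table: minute values must lie in 1..1440")
  if (anyDuplicated(dt, by = c("subject_id", "day", "minute")))
    stopf("read_epoch_table: duplicate (subject, day, minute) rows")
  out <- list()
  for (sid in unique(dt$subject_id)) {
    sub <- dt[dt$subject_id == sid]
    nd <- max(sub$day)
    counts <- integer(nd * 1440L)
    idx <- (sub$day - 1L) * 1440L + sub$minute
    counts[idx] <- sub$counts
    if (nrow(sub) < nd * 1440L)
      warnf("read_epoch_table: subject %s missing %d minutes; zero-filled",
            sid, nd * 1440L - nrow(sub))
    out[[sid]] <- epoch_series(sid, counts)
  }
  out
}

#' Convert a PAXRAW-style table to the package's epoch schema
#'
#' Adapter for tables using the national physical-activity-monitor field
#' names: `SEQN` (respondent id) -> `subject_id`, `PAXDAY` -> `day`,
#' `PAXN` -> minute-of-day 1..1440, `PAXINTEN` (device intensity) ->
#' `counts`. Input `PAXN` may alternatively run sequentially over the whole
#' record (1..n_days*1440); it is folded to minute-of-day.
#'
#' @param path CSV with the PAXRAW-style columns.
#' @param out optional output CSV path; when given, the converted table is
#'   written and the path returned invisibly.
#' @return named list of [epoch_series()] (or `out`, invisibly).
#' @export
read_paxraw <- function(path, out = NULL) {
  dt <- data.table::fread(path)
  need <- c("SEQN", "PAXDAY", "PAXN", "PAXINTEN")
  if (!all(need %in% names(dt)))
    stopf("read_paxraw: missing columns %s",
          paste(setdiff(need, names(dt)), collapse = ", "))
  conv <- data.table::data.table(
    subject_id = as.character(dt$SEQN), day = dt$PAXDAY,
    minute = ((dt$PAXN - 1L) %% 1440L) + 1L, counts = dt$PAXINTEN)
  if (!is.null(out)) {
    data.table::fwrite(conv, out)
    return(invisible(out))
  }
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  data.table::fwrite(conv, tmp)
  read_epoch_table(tmp)
}

#' Non-wear detection parameters
#'
#' Defaults follow the wear-time convention published alongside national
#' actigraphy releases: a non-wear interval is at least 60 consecutive
#' minutes of zero counts, allowing up to 2 interruption minutes with counts
#' under 100; any count at or above the ceiling terminates the interval.
#'
#' @param min_window_minutes minimum interval length (default 60).
#' @param spike_allowance_minutes tolerated interruption minutes (default 2).
#' @param spike_ceiling exclusive upper count bound for an interruption
#'   minute (default 100).
#' @return object of class `nonwear_params`.
#' @export
nonwear_params <- function(min_window_minutes = 60L,
                           spike_allowance_minutes = 2L,
                           spike_ceiling = 100L) {
  if (!is_count(min_window_minutes))
    stopf("nonwear_params: min_window_minutes must be >= 1")
  if (spike_allowance_minutes < 0)
    stopf("nonwear_params: spike_allowance_minutes must be >= 0")
  structure(list(min_window_minutes = as.integer(min_window_minutes),
                 spike_allowance_minutes = as.integer(spike_allowance_minutes),
                 spike_ceiling = as.integer(spike_ceiling)),
            class = "nonwear_params")
}

#' Detect non-wear minutes
#'
#' A minute is non-wear iff it lies in some window of length at least
#' `min_window_minutes` whose counts are all below `spike_ceiling` with at
#' most `spike_allowance_minutes` nonzero minutes (interruption minutes
#' inside a qualifying window are themselves labeled non-wear). Implemented
#' as a linear-time sweep: for each start position the maximal admissible end
#' is monotone, and the union of all qualifying windows is marked.
#'
#' @param series an [epoch_series()].
#' @param params a [nonwear_params()].
#' @return object of class `wear_mask`: logical `wear` aligned to the counts
#'   and a `bouts` data.frame of maximal wear runs (`start`, `length`).
#' @export
detect_nonwear <- function(series, params = nonwear_params()) {
  x <- series$counts
  n <- length(x)
  minw <- params$min_window_minutes
  allow <- params$spike_allowance_minutes
  ceil <- params$spike_ceiling
  spike <- x > 0L & x < ceil
  bigpos <- which(x >= ceil)
  spikepos <- which(spike)
  cs <- cumsum(spike)
  # next count >= ceiling at or after each position
  nxt_big <- rep.int(n + 1L, n)
  if (length(bigpos)) {
    idx <- findInterval(seq_len(n) - 1L, bigpos) + 1L
    has <- idx <= length(bigpos)
    nxt_big[has] <- bigpos[idx[has]]
  }
  # for start i, window may run until just before the (allow+1)-th spike
  k <- cs - spike + allow + 1L  # index into spikepos of first disqualifying spike
  spike_bound <- rep.int(n + 1L, n)
  has <- k <= length(spikepos)
  spike_bound[has] <- spikepos[k[has]]
  jmax <- pmin(nxt_big, spike_bound) - 1L
  jmax <- pmin(jmax, n)
  starts <- which(jmax - seq_len(n) + 1L >= minw)
  nonwear <- logical(n)
  if (length(starts)) {
    # union of [start, jmax(start)] via a difference array
    delta <- tabulate(starts, n + 1L) - tabulate(jmax[starts] + 1L, n + 1L)
    nonwear <- cumsum(delta)[seq_len(n)] > 0L
  }
  wear <- !nonwear
  r <- rle(wear)
  ends <- cumsum(r$lengths)
  starts_r <- ends - r$lengths + 1L
  bouts <- data.frame(start = starts_r[r$values], length = r$lengths[r$values])
  structure(list(wear = wear, bouts = bouts), class = "wear_mask")
}

#' Summarize wear time from a mask
#'
#' @param mask a `wear_mask`.
#' @return list: `total_wear_minutes`, `n_bouts`, `mean_bout_length`,
#'   `max_bout_length`.
#' @export
weartime_summary <- function(mask) {
  nb <- nrow(mask$bouts)
  list(total_wear_minutes = sum(mask$wear),
       n_bouts = nb,
       mean_bout_length = if (nb) mean(mask$bouts$length) else 0,
       max_bout_length = if (nb) max(mask$bouts$length) else 0)
}

#' Apply the half-week compliance filter
#'
#' A subject is included when total wear minutes reach `threshold_fraction`
#' of the expected wear window, `n_days * daily_window_minutes` (default 900
#' daytime minutes per day, since devices were off at night). The
#' alternative "valid days" interpretation counts days with at least
#' `valid_day_minutes` of wear and requires `threshold_fraction` of days.
#'
#' @param masks named list of `wear_mask`, one per subject.
#' @param threshold_fraction inclusion threshold in (0, 1\] (default 0.5).
#' @param n_days days per subject (default 7).
#' @param daily_window_minutes expected daily wear window (default 900).
#' @param mode `"minutes"` (default) or `"days"`.
#' @param valid_day_minutes wear minutes defining a valid day in `"days"`
#'   mode (default 600).
#' @return list: `included`, `excluded` (character ids) and `report`
#'   (data.frame of per-subject wear fractions).
#' @export
compliance_filter <- function(masks, threshold_fraction = 0.5, n_days = 7,
                              daily_window_minutes = 900,
                              mode = c("minutes", "days"),
                              valid_day_minutes = 600) {
  mode <- match.arg(mode)
  if (length(masks) == 0) stopf("compliance_filter: empty cohort")
  if (threshold_fraction <= 0 || threshold_fraction > 1)
    stopf("compliance_filter: threshold_fraction must lie in (0, 1]")
  ids <- names(masks)
  if (mode == "minutes") {
    wearmin <- vapply(masks, function(m) sum(m$wear), numeric(1))
    frac <- wearmin / (n_days * daily_window_minutes)
  } else {
    frac <- vapply(masks, function(m) {
      w <- m$wear
      nd <- length(w) %/% 1440L
      daymin <- vapply(seq_len(nd), function(d)
        sum(w[((d - 1L) * 1440L + 1L):(d * 1440L)]), numeric(1))
      mean(daymin >= valid_day_minutes)
    }, numeric(1))
  }
  inc <- frac >= threshold_fraction
  list(included = ids[inc], excluded = ids[!inc],
       report = data.frame(subject_id = ids, wear_fraction = unname(frac),
                           included = unname(inc), stringsAsFactors = FALSE))
}
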