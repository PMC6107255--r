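# centered moving average; the window spans ~width_epochs epochs (forced
# odd), shrinking at the edges so no epoch is dropped
moving_avg <- function(x, width_epochs) {
  w <- as.integer(width_epochs)
  if (w <= 1L) return(as.numeric(x))
  if (w %% 2L == 0L) w <- w + 1L
  half <- w %/% 2L
  n <- length(x)
  cc <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cc[hi + 1L] - cc[lo]) / (hi - lo + 1L)
}

#' Actogram matrix
#'
#' Arranges a recording as a day-by-time raster of binned counts, the
#' standard visualisation of rest-activity rhythms.  When `double_plot` is
#' set each row spans 48 h (day *d* followed by day *d + 1*), which makes
#' phase drift easier to see.
#'
#' @param series an [epoch_series()].
#' @param bin_minutes width of the plotting bins.
#' @param double_plot logical; double-plotted rows span 48 h.
#' @param day_start clock time at which rows begin.
#' @return a matrix with class `"actogram"`; attributes `bin_minutes`,
#'   `double_plotted` and `day_start`.
#' @export
actogram_matrix <- function(series, bin_minutes = 10, double_plot = FALSE,
                            day_start = "09:00") {
  segs <- segment_days(series, day_start)
  if (!is.null(attr(segs, "trailing"))) {
    message("actogram_matrix: trimmed incomplete final day (",
            length(attr(segs, "trailing")), " epochs)")
  }
  rows <- lapply(segs, function(d) bin_counts(d, bin_minutes * 60L)$counts)
  if (double_plot) {
    if (length(rows) < 2L) {
      stop("double plotting requires at least 2 complete days", call. = FALSE)
    }
    rows <- lapply(seq_len(length(rows) - 1L),
                   function(r) c(rows[[r]], rows[[r + 1L]]))
  }
  structure(do.call(rbind, rows), class = c("actogram", "matrix"),
            bin_minutes = bin_minutes, double_plotted = double_plot,
            day_start = clock_time(day_start))
}

#' @export
plot.actogram <- function(x, col = grDevices::grey.colors(64, start = 1,
                                                          end = 0),
                          ...) {
  m <- unclass(x)
  hours <- ncol(m) * attr(x, "bin_minutes") / 60
  graphics::image(x = seq(0, hours, length.out = ncol(m) + 1L),
                  y = seq_len(nrow(m) + 1L) - 0.5,
                  z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = col, xlab = sprintf("hours from %s",
                                            format(attr(x, "day_start"))),
                  ylab = "day", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(seq_len(nrow(m))))
  invisible(x)
}

#' Per-day daytime and nighttime activity totals
#'
#' Partitions each complete recording day's counts by a daytime clock
#' window (default 06:30 to 19:00, the observed activity onset and
#' quiescence start); the complement is nighttime.  Daytime plus nighttime
#' equals the daily total by construction.
#'
#' @param series an [epoch_series()].
#' @param daytime length-2 vector of clock times `c(start, end)`.
#' @param day_start clock time at which a recording day begins.
#' @return a data frame with class `"diurnal_summary"`: one row per day
#'   with `daytime_total`, `nighttime_total`, `daily_total`.
#' @export
diurnal_summary <- function(series, daytime = c("06:30", "19:00"),
                            day_start = "09:00") {
  segs <- segment_days(series, day_start)
  a <- as_clock_min(daytime[[1L]])
  b <- as_clock_min(daytime[[2L]])
  out <- do.call(rbind, lapply(seq_along(segs), function(d) {
    day <- segs[[d]]
    clock <- epoch_clock_min(day)
    in_day <- if (a < b) clock >= a & clock < b else clock >= a | clock < b
    data.frame(day = d,
               daytime_total = sum(day$counts[in_day]),
               nighttime_total = sum(day$counts[!in_day]),
               daily_total = sum(day$counts))
  }))
  structure(out, class = c("diurnal_summary", "data.frame"),
            daytime = clock_time(c(a, b)))
}

#' Detect the daytime activity onset of a day
#'
#' The onset is the first clock time after the day's main quiescent period
#' (the longest sub-threshold run, treating the day as circular) at which
#' the raw count reaches a fraction of the day's peak smoothed activity
#' while the smoothed activity stays at or above that threshold for the
#' sustain period.  Requiring the raw count as well keeps the estimate from
#' drifting into the quiescent side of the centered smoother; anchoring to
#' the main quiescent period makes the result independent of where the
#' recording day happens to begin (recording days usually start at 09:00,
#' mid-activity).
#'
#' @param day an `epoch_series` covering one recording day.
#' @param threshold_frac fraction of the peak smoothed activity.
#' @param sustain_minutes how long the smoothed activity must stay above
#'   threshold.
#' @param smooth_minutes centered smoothing window.
#' @return the onset as a [clock_time()].
#' @export
detect_activity_onset <- function(day, threshold_frac = 0.2,
                                  sustain_minutes = 10,
                                  smooth_minutes = 10) {
  stopifnot(inherits(day, "epoch_series"))
  if (all(day$counts == 0)) {
    stop("no onset detected: day has no activity", call. = FALSE)
  }
  epm <- day$epoch_seconds / 60
  sm <- moving_avg(day$counts, smooth_minutes / epm)
  thr <- threshold_frac * max(sm)
  sus <- max(1L, as.integer(round(sustain_minutes / epm)))
  n <- length(sm)
  # rotate the day to begin just after the longest sub-threshold run
  below <- sm < thr
  rot <- 0L
  if (any(below) && !all(below)) {
    r <- rle(c(below, below))
    ends <- cumsum(r$lengths)
    runs <- which(r$values & ends <= 2L * n)
    longest <- runs[which.max(r$lengths[runs])]
    rot <- ends[longest] %% n
  }
  ord <- ((seq_len(n) - 1L + rot) %% n) + 1L
  ok_run <- sustained_at_least(sm[ord] >= thr, sus)
  cand <- which(day$counts[ord] >= thr & ok_run)
  if (!length(cand)) {
    stop("no onset detected: criterion never met", call. = FALSE)
  }
  clock_time(epoch_clock_min(day)[ord[cand[1L]]])
}

# TRUE at i when flags[i..i+len-1] are all TRUE (runs truncated at the end
# still count if they reach the boundary)
sustained_at_least <- function(flags, len) {
  n <- length(flags)
  idx_false <- which(!flags)
  next_false <- findInterval(seq_len(n) - 1L, idx_false) + 1L
  nf <- c(idx_false, n + 1L)[pmin(next_false, length(idx_false) + 1L)]
  flags & (nf - seq_len(n) >= len | nf > n)
}

#' Detect diurnal activity peaks
#'
#' Finds local maxima of a smoothed mean 24-h profile that rise at least a
#' prominence fraction of the profile's range above its minimum.  The
#' profile wraps around the day boundary.  Healthy marmosets show a
#' biphasic profile with peaks near 10:00 and 16:00.
#'
#' @param profile an [hourly_profile()] (averaged across days) or a numeric
#'   vector of binned mean counts for one day.
#' @param bin_minutes bin width of `profile` when given as a vector
#'   (ignored for an `hourly_profile`, which is hourly).
#' @param smooth_bins centered smoothing window in bins (odd; 1 = none).
#' @param prominence_frac fraction of the profile range a peak must rise
#'   above the minimum.
#' @param day_start clock time of the first bin.
#' @return a [clock_time()] vector of peak bin starts, ordered by time; may
#'   be empty.
#' @export
detect_peaks <- function(profile, bin_minutes = 60, smooth_bins = 3,
                         prominence_frac = 0.1, day_start = "09:00") {
  if (inherits(profile, "hourly_profile")) {
    day_start <- attr(profile, "day_start")
    profile <- colMeans(unclass(profile))
    bin_minutes <- 60
  }
  x <- as.numeric(profile)
  n <- length(x)
  if (n * bin_minutes != 1440) {
    stop("profile must cover exactly 24 h", call. = FALSE)
  }
  w <- as.integer(smooth_bins)
  if (w > 1L) {
    if (w %% 2L == 0L) w <- w + 1L
    half <- w %/% 2L
    xx <- c(utils::tail(x, half), x, utils::head(x, half))
    x <- as.numeric(stats::filter(xx, rep(1 / w, w), sides = 2))[
      (half + 1L):(half + n)]
  }
  rng <- max(x) - min(x)
  if (rng == 0) return(clock_time(integer(0)))
  left <- x[c(n, seq_len(n - 1L))]
  right <- x[c(seq_len(n)[-1L], 1L)]
  is_peak <- x > left & x >= right & (x - min(x)) >= prominence_frac * rng
  onset <- (as_clock_min(day_start) + (which(is_peak) - 1L) * bin_minutes) %%
    1440
  clock_time(sort(onset))
}

#' Post-dose activity response
#'
#' Characterises the transient activity increase that follows an oral
#' L-DOPA dose.  The pre-dose baseline window (2.5 h by default, matching
#' the recording protocol of dosing at 11:30 after a 09:00 start) supplies
#' a mean and SD; the response onset is the first post-dose time at which
#' the raw count exceeds `mean + k * SD` while the smoothed activity stays
#' above that threshold for the sustain period, the response ends when that
#' stops being true, the peak is the maximum of the smoothed activity
#' within the response, and the AUC integrates smoothed activity above the
#' baseline mean over the response.  A vehicle day, where the threshold is
#' never crossed, yields `response = FALSE`.
#'
#' @param series an [epoch_series()] covering the baseline window and at
#'   least 5 h after the dose.
#' @param dose_time absolute dose time (`POSIXct` or parseable string).
#' @param baseline_minutes length of the pre-dose baseline window.
#' @param smooth_minutes centered smoothing window.
#' @param k threshold in baseline SDs above the baseline mean.
#' @param sustain_minutes how long the smoothed activity must hold the
#'   threshold.
#' @param max_response_hours how far after the dose to search; keeps the
#'   evening activity peak and the next morning's activity out of the
#'   response window.
#' @return an object of class `"dose_response"` with fields
#'   `baseline_mean`, `baseline_sd`, `response` (logical),
#'   `onset_latency_min`, `peak_time_min`, `response_duration_min`,
#'   `response_auc`.
#' @export
dose_response <- function(series, dose_time, baseline_minutes = 150,
                          smooth_minutes = 10, k = 2, sustain_minutes = 5,
                          max_response_hours = 6) {
  stopifnot(inherits(series, "epoch_series"))
  dose_time <- as_start_time(dose_time)
  epm <- series$epoch_seconds / 60
  i_dose <- as.numeric(difftime(dose_time, series$start, units = "secs")) /
    series$epoch_seconds + 1
  if (abs(i_dose - round(i_dose)) > 1e-9) {
    stop("dose_time does not fall on the epoch grid", call. = FALSE)
  }
  i_dose <- as.integer(round(i_dose))
  n_base <- as.integer(round(baseline_minutes / epm))
  if (i_dose - n_base < 1L) {
    stop("series does not cover the ", baseline_minutes,
         " min baseline window before the dose", call. = FALSE)
  }
  n <- length(series$counts)
  if (n - i_dose + 1L < as.integer(round(300 / epm))) {
    stop("series must cover at least 5 h after the dose", call. = FALSE)
  }
  base <- series$counts[(i_dose - n_base):(i_dose - 1L)]
  mu <- mean(base)
  sdev <- stats::sd(base)
  thr <- mu + k * sdev
  i_end <- min(n, i_dose + as.integer(round(max_response_hours * 60 / epm)) -
                 1L)
  sm <- moving_avg(series$counts, smooth_minutes / epm)
  post <- i_dose:i_end
  sus <- max(1L, as.integer(round(sustain_minutes / epm)))
  ok_run <- sustained_at_least(sm[post] >= thr, sus)
  cand <- which(series$counts[post] >= thr & ok_run)
  res <- list(baseline_mean = mu, baseline_sd = sdev, threshold = thr,
              dose_time = dose_time)
  if (!length(cand)) {
    res <- c(res, list(response = FALSE, onset_latency_min = NA_real_,
                       peak_time_min = NA_real_,
                       response_duration_min = NA_real_, response_auc = 0))
    class(res) <- "dose_response"
    return(res)
  }
  on_i <- cand[1L]
  # last epoch of the response: raw above threshold with the smoothed
  # activity holding the threshold over the trailing sustain period
  held <- rev(sustained_at_least(rev(sm[post] >= thr), sus))
  above <- which(series$counts[post] >= thr & held)
  end_i <- if (any(above >= on_i)) max(above[above >= on_i]) else on_i
  seg <- post[on_i:end_i]
  peak_i <- seg[which.max(sm[seg])]
  res <- c(res, list(
    response = TRUE,
    onset_latency_min = (on_i - 1L) * epm,
    peak_time_min = (peak_i - i_dose) * epm,
    response_duration_min = (end_i - on_i + 1L) * epm,
    response_auc = sum(pmax(sm[seg] - mu, 0)) * epm))
  class(res) <- "dose_response"
  res
}

#' @export
print.dose_response <- function(x, digits = 2, ...) {
  cat("<dose_response> dose at",
      format(x$dose_time, "%Y-%m-%d %H:%M"), "\n")
  cat("  baseline  ", format(round(x$baseline_mean, digits)), "\u00b1",
      format(round(x$baseline_sd, digits)), "counts/epoch\n")
  if (!x$response) {
    cat("  no response (threshold never crossed)\n")
    return(invisible(x))
  }
  cat("  onset     ", format(round(x$onset_latency_min, 1)), "min after dose\n")
  cat("  peak      ", format(round(x$peak_time_min, 1)), "min after dose\n")
  cat("  duration  ", format(round(x$response_duration_min, 1)), "min\n")
  cat("  AUC       ", format(round(x$response_auc)), "count\u00b7min above baseline\n")
  invisible(x)
}
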