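#' Day-by-hour activity profile
#'
#' Sums counts into 24 hourly bins per complete recording day; the matrix
#' feeds the nonparametric circadian indices.  Masked (missing) epochs
#' inside a complete day are refused: the indices assume complete data.
#'
#' @param series an [epoch_series()].
#' @param day_start clock time at which a recording day begins.
#' @return an `n_days x 24` matrix with class `"hourly_profile"`; row `d`,
#'   column `h` holds the summed counts of hour `h` (1-based from
#'   `day_start`) of day `d`.
#' @export
hourly_profile <- function(series, day_start = "09:00") {
  segs <- segment_days(series, day_start)
  rows <- lapply(segs, function(day) {
    if (n_missing(day) > 0L) {
      stop("NPCRA requires complete data: masked epochs inside a complete day",
           call. = FALSE)
    }
    bin_counts(day, 3600L)$counts
  })
  structure(do.call(rbind, rows), class = c("hourly_profile", "matrix"),
            day_start = attr(segs, "day_start"))
}

# chronological hourly sequence (day 1 hour 1, ..., day n hour 24)
profile_sequence <- function(profile) as.vector(t(unclass(profile)))

#' Inter-daily stability (IS)
#'
#' The degree of regularity of the 24-h activity-rest pattern: the ratio of
#' the variance of the average hourly profile to the overall variance of
#' the hourly series,
#' \deqn{IS = \frac{N \sum_{h=1}^{24} (\bar x_h - \bar x)^2}
#'                 {24 \sum_{i=1}^{N} (x_i - \bar x)^2},}
#' where \eqn{x_i} is the chronological hourly sequence, \eqn{\bar x_h} the
#' mean of hour \eqn{h} across days, and \eqn{N} the number of hourly
#' samples.  IS lies in \[0, 1\]; 1 means a perfectly repeated daily
#' pattern.
#'
#' @param profile an [hourly_profile()] (or plain day-by-hour matrix) with
#'   at least 2 complete days.
#' @return IS, a number in \[0, 1\].
#' @export
interdaily_stability <- function(profile) {
  x <- unclass(profile)
  if (!is.matrix(x) || ncol(x) != 24L) {
    stop("profile must be a day-by-hour matrix with 24 columns", call. = FALSE)
  }
  if (nrow(x) < 2L) stop("IS requires at least 2 complete days", call. = FALSE)
  N <- length(x)
  xbar <- mean(x)
  denom <- sum((x - xbar)^2)
  if (denom == 0) {
    stop("undefined: constant series has no variance", call. = FALSE)
  }
  hour_means <- colMeans(x)
  N * sum((hour_means - xbar)^2) / (24 * denom)
}

#' Intra-daily variability (IV)
#'
#' The degree of fragmentation of the activity-rest pattern: the normalised
#' mean squared successive difference of the chronological hourly sequence,
#' \deqn{IV = \frac{N \sum_{i=2}^{N} (x_i - x_{i-1})^2}
#'                 {(N-1) \sum_{i=1}^{N} (x_i - \bar x)^2}.}
#' IV is near 2 for white noise, about 4 for a strictly alternating
#' sequence, and small for a smooth rhythm (for a pure 24-h cosine sampled
#' hourly it approaches \eqn{2(1 - \cos(2\pi/24)) \approx 0.068}).
#'
#' @param profile an [hourly_profile()] or day-by-hour matrix supplying at
#'   least 25 hourly samples.
#' @return IV, a non-negative number.
#' @export
intradaily_variability <- function(profile) {
  x <- profile_sequence(profile)
  N <- length(x)
  if (N < 25L) stop("IV requires at least 25 hourly samples", call. = FALSE)
  denom <- sum((x - mean(x))^2)
  if (denom == 0) {
    stop("undefined: constant series has no variance", call. = FALSE)
  }
  N * sum(diff(x)^2) / ((N - 1) * denom)
}

#' Least- or most-active window of a day
#'
#' Scans every window of `window_hours` hours at `step_minutes` onset
#' resolution, wrapping around the day boundary, and returns the window
#' minimising (`mode = "least"`, as for L5) or maximising
#' (`mode = "most"`, as for M10) mean activity.  Ties are broken by the
#' earliest onset after the day start.
#'
#' @param day an `epoch_series` covering exactly 24 h (one recording day).
#' @param window_hours window length in hours (5 for L5, 10 for M10).
#' @param mode `"least"` or `"most"`.
#' @param step_minutes onset grid resolution; must divide 60 and be a
#'   multiple of the epoch length.
#' @return a list with class `"window_stat"`: `mean_activity` (counts per
#'   hour averaged over the window), `onset` (clock time of window start)
#'   and `window_hours`.
#' @export
extreme_window <- function(day, window_hours, mode = c("least", "most"),
                           step_minutes = 60) {
  mode <- match.arg(mode)
  stopifnot(inherits(day, "epoch_series"))
  n <- length(day$counts)
  if (n * day$epoch_seconds != 86400L) {
    stop("day must span exactly 24 h", call. = FALSE)
  }
  if (window_hours >= 24 || window_hours <= 0) {
    stop("window_hours must lie strictly between 0 and 24", call. = FALSE)
  }
  if (60 %% step_minutes != 0 && step_minutes %% 60 != 0) {
    stop("step_minutes must divide 60 (or be a multiple of it)",
         call. = FALSE)
  }
  step_ep <- step_minutes * 60 / day$epoch_seconds
  win_ep <- window_hours * 3600 / day$epoch_seconds
  if (step_ep != round(step_ep) || win_ep != round(win_ep)) {
    stop("step and window must be whole numbers of epochs", call. = FALSE)
  }
  cc <- cumsum(c(0, day$counts, day$counts))
  offsets <- seq(0L, n - 1L, by = as.integer(step_ep))
  sums <- cc[offsets + win_ep + 1L] - cc[offsets + 1L]
  pick <- if (mode == "least") which.min(sums) else which.max(sums)
  onset_min <- (as_clock_min(clock_time(epoch_clock_min(day)[1L])) +
                  offsets[pick] * day$epoch_seconds / 60) %% 1440
  structure(list(mean_activity = sums[pick] / window_hours,
                 onset = clock_time(onset_min),
                 window_hours = window_hours,
                 mode = mode),
            class = "window_stat")
}

#' @export
print.window_stat <- function(x, ...) {
  cat(sprintf("<window_stat> %s-active %g h: onset %s, mean %s counts/h\n",
              x$mode, x$window_hours, format(x$onset),
              format(round(x$mean_activity, 2))))
  invisible(x)
}

#' Rhythm amplitude and relative amplitude
#'
#' Amplitude is the difference between the M10 and L5 mean activity levels;
#' relative amplitude normalises it by their sum,
#' \eqn{RA = (M10 - L5)/(M10 + L5)}, giving a 0-1 index of rhythm strength.
#'
#' @param m10 mean activity of the most active 10-hour window.
#' @param l5 mean activity of the least active 5-hour window.
#' @return `rhythm_amplitude()`: `m10 - l5`; `relative_amplitude()`: RA in
#'   \[0, 1\].
#' @export
relative_amplitude <- function(m10, l5) {
  if (any(l5 < 0) || any(m10 < l5)) {
    stop("require m10 >= l5 >= 0", call. = FALSE)
  }
  if (any(m10 + l5 == 0)) {
    stop("undefined: no activity (m10 + l5 = 0)", call. = FALSE)
  }
  (m10 - l5) / (m10 + l5)
}

#' @rdname relative_amplitude
#' @export
rhythm_amplitude <- function(m10, l5) {
  if (any(l5 < 0) || any(m10 < l5)) {
    stop("require m10 >= l5 >= 0", call. = FALSE)
  }
  m10 - l5
}

#' Nonparametric circadian rhythm summary
#'
#' Computes IS and IV once on the full record (pooled hourly sequence) and
#' L5, M10, amplitude and relative amplitude per recording day, then
#' summarises the per-day quantities as mean and SD across days.  Window
#' onsets are averaged as minutes since the day start (not circularly);
#' with day boundaries at 09:00, both the nocturnal L5 and diurnal M10
#' windows fall well inside one day segment, where the linear average is
#' exact.
#'
#' @param series an [epoch_series()] holding at least 2 complete days.
#' @param day_start clock time at which a recording day begins.
#' @param step_minutes onset grid for the L5/M10 scan.
#' @return an object of class `"npcra_result"` with elements `is`, `iv`,
#'   `per_day` (data frame of per-day L5/M10/amplitude/RA and onsets) and
#'   `summary` (mean and SD of each).
#' @export
npcra_summary <- function(series, day_start = "09:00", step_minutes = 60) {
  segs <- segment_days(series, day_start)
  if (length(segs) < 2L) {
    stop("NPCRA summary requires at least 2 complete days", call. = FALSE)
  }
  profile <- hourly_profile(series, day_start)
  ds_min <- as_clock_min(attr(profile, "day_start"))
  per_day <- do.call(rbind, lapply(seq_along(segs), function(d) {
    l5 <- extreme_window(segs[[d]], 5, "least", step_minutes)
    m10 <- extreme_window(segs[[d]], 10, "most", step_minutes)
    data.frame(
      day = d,
      l5 = l5$mean_activity,
      l5_onset_min = (as_clock_min(l5$onset) - ds_min) %% 1440,
      m10 = m10$mean_activity,
      m10_onset_min = (as_clock_min(m10$onset) - ds_min) %% 1440,
      amplitude = rhythm_amplitude(m10$mean_activity, l5$mean_activity),
      relative_amplitude = relative_amplitude(m10$mean_activity,
                                              l5$mean_activity))
  }))
  ms <- function(v) c(mean = mean(v), sd = stats::sd(v))
  summary <- list(
    l5 = ms(per_day$l5), m10 = ms(per_day$m10),
    amplitude = ms(per_day$amplitude),
    relative_amplitude = ms(per_day$relative_amplitude),
    l5_onset = c(mean = clock_time((ds_min + mean(per_day$l5_onset_min)) %%
                                     1440),
                 sd_min = stats::sd(per_day$l5_onset_min)),
    m10_onset = c(mean = clock_time((ds_min + mean(per_day$m10_onset_min)) %%
                                      1440),
                  sd_min = stats::sd(per_day$m10_onset_min)))
  structure(list(is = interdaily_stability(profile),
                 iv = intradaily_variability(profile),
                 per_day = per_day, summary = summary,
                 n_days = length(segs), day_start = clock_time(day_start),
                 subject_id = series$subject_id),
            class = "npcra_result")
}

#' @export
print.npcra_result <- function(x, digits = 3, ...) {
  s <- x$summary
  fmt <- function(v) paste0(format(round(v[["mean"]], digits)), " \u00b1 ",
                            format(round(v[["sd"]], digits)))
  fmt_on <- function(v) {
    paste0(format(clock_time(v[["mean"]])), " \u00b1 ",
           format(round(v[["sd_min"]])), " min")
  }
  cat("<npcra_result> subject", x$subject_id, "-", x$n_days,
      "days from", format(x$day_start), "\n")
  cat("  IS         ", format(round(x$is, digits)), "\n")
  cat("  IV         ", format(round(x$iv, digits)), "\n")
  cat("  L5         ", fmt(s$l5), "\n")
  cat("  L5 onset   ", fmt_on(s$l5_onset), "\n")
  cat("  M10        ", fmt(s$m10), "\n")
  cat("  M10 onset  ", fmt_on(s$m10_onset), "\n")
  cat("  Amplitude  ", fmt(s$amplitude), "\n")
  cat("  Rel Amp    ", fmt(s$relative_amplitude), "\n")
  invisible(x)
}

#' @rdname npcra_summary
#' @param x an `npcra_result`.
#' @param row.names,optional,... conventional arguments; unused.
#' @export
as.data.frame.npcra_result <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  s <- x$summary
  data.frame(subject = x$subject_id, n_days = x$n_days, is = x$is, iv = x$iv,
             l5_mean = s$l5[["mean"]], l5_sd = s$l5[["sd"]],
             l5_onset = format(clock_time(s$l5_onset[["mean"]])),
             l5_onset_sd_min = s$l5_onset[["sd_min"]],
             m10_mean = s$m10[["mean"]], m10_sd = s$m10[["sd"]],
             m10_onset = format(clock_time(s$m10_onset[["mean"]])),
             m10_onset_sd_min = s$m10_onset[["sd_min"]],
             amplitude_mean = s$amplitude[["mean"]],
             amplitude_sd = s$amplitude[["sd"]],
             rel_amp_mean = s$relative_amplitude[["mean"]],
             rel_amp_sd = s$relative_amplitude[["sd"]])
}
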