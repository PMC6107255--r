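# constant-count series starting at a given wall-clock time
make_series <- function(hours, value = 1, start = "2018-06-01 09:00",
                        epoch_seconds = 60L, ...) {
  epoch_series(rep(value, hours * 3600 / epoch_seconds), start,
               epoch_seconds, ...)
}

# one 24-h day (hourly epochs) from a vector of 24 hourly totals
hourly_day <- function(values, start = "2018-06-01 00:00") {
  stopifnot(length(values) == 24L)
  epoch_series(values, start, 3600L)
}

# mean sleep metric over all complete days of a simulated record
mean_sleep_metric <- function(series, field, ...) {
  days <- segment_days(series)
  mean(vapply(days, function(d) {
    compute_sleep_metrics(d, ...)[[field]]
  }, numeric(1)))
}

# brute-force oracle for extreme_window: enumerate every wrapped window
brute_extreme <- function(counts, epoch_seconds, window_hours, mode,
                          step_minutes = 60) {
  n <- length(counts)
  win_ep <- window_hours * 3600 / epoch_seconds
  step_ep <- step_minutes * 60 / epoch_seconds
  doubled <- c(counts, counts)
  offsets <- seq(0L, n - 1L, by = step_ep)
  sums <- vapply(offsets, function(o) sum(doubled[(o + 1):(o + win_ep)]),
                 numeric(1))
  pick <- if (mode == "least") which.min(sums) else which.max(sums)
  list(mean_activity = sums[pick] / window_hours,
       offset_min = offsets[pick] * epoch_seconds / 60)
}

# literal two-pass implementations of the circadian indices
oracle_is <- function(mat) {
  x <- as.vector(t(mat))
  length(x) * sum((colMeans(mat) - mean(x))^2) /
    (ncol(mat) * sum((x - mean(x))^2))
}
oracle_iv <- function(mat) {
  x <- as.vector(t(mat))
  n <- length(x)
  n * sum(diff(x)^2) / ((n - 1) * sum((x - mean(x))^2))
}
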