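#' Split a recording into 24-hour recording days
#'
#' A recording day is the 24 h starting at `day_start` on the wall clock
#' (09:00 by default, the usual collar-deployment time).  Epochs before the
#' first occurrence of `day_start` and after the last complete day are
#' returned as trimmed remainders rather than silently dropped.
#'
#' @param series an [epoch_series()].
#' @param day_start clock time at which a recording day begins.
#' @return an object of class `"day_segments"`: a list of `epoch_series`,
#'   one per complete day, with attributes `leading` and `trailing` holding
#'   the trimmed remainder series (or `NULL`), and `day_start`.
#' @examples
#' s <- epoch_series(rep(1, 72 * 60), "2018-06-01 09:00")
#' length(segment_days(s))
#' @export
segment_days <- function(series, day_start = "09:00") {
  stopifnot(inherits(series, "epoch_series"))
  ds <- as_clock_min(day_start)
  n <- length(series$counts)
  per_day <- 86400L %/% series$epoch_seconds
  if (86400L %% series$epoch_seconds != 0L) {
    stop("epoch length must divide 24 h", call. = FALSE)
  }
  clock <- epoch_clock_min(series)
  first <- which(abs(clock - ds) < 1e-9)[1L]
  if (is.na(first)) {
    stop("insufficient span: day start ", format(clock_time(day_start)),
         " never falls on the epoch grid of the series", call. = FALSE)
  }
  n_days <- (n - first + 1L) %/% per_day
  if (n_days < 1L) {
    stop("insufficient span: series holds no complete day from first ",
         format(clock_time(day_start)), call. = FALSE)
  }
  segs <- lapply(seq_len(n_days) - 1L, function(d) {
    epoch_slice(series, first + d * per_day, first + (d + 1L) * per_day - 1L)
  })
  leading <- if (first > 1L) epoch_slice(series, 1L, first - 1L)
  last_used <- first + n_days * per_day - 1L
  trailing <- if (last_used < n) epoch_slice(series, last_used + 1L, n)
  structure(segs, class = "day_segments", day_start = clock_time(day_start),
            leading = leading, trailing = trailing)
}

#' @export
print.day_segments <- function(x, ...) {
  lead <- attr(x, "leading"); trail <- attr(x, "trailing")
  cat("<day_segments>", length(x), "complete day(s) starting",
      format(attr(x, "day_start")), "\n")
  if (!is.null(lead)) cat("  leading remainder :", length(lead), "epochs\n")
  if (!is.null(trail)) cat("  trailing remainder:", length(trail), "epochs\n")
  invisible(x)
}

#' Clip a clock window out of a series
#'
#' Extracts the first full occurrence of the clock window `start` to `end`.
#' Windows with `end <= start` cross midnight (the default sleep window
#' 19:00 to 06:30 spans 11.5 h); `end == start` means a full 24 h.
#'
#' @param series an [epoch_series()].
#' @param start,end clock times bounding the window.
#' @return an `epoch_series` spanning exactly the window duration.
#' @export
clip_window <- function(series, start, end) {
  stopifnot(inherits(series, "epoch_series"))
  span_min <- clock_span_min(start, end)
  n_epochs <- span_min * 60L / series$epoch_seconds
  if (n_epochs != round(n_epochs)) {
    stop("window duration is not a whole number of epochs", call. = FALSE)
  }
  clock <- epoch_clock_min(series)
  first <- which(abs(clock - as_clock_min(start)) < 1e-9)[1L]
  if (is.na(first)) {
    stop("window not contained: ", format(clock_time(start)),
         " never falls on the epoch grid of the series", call. = FALSE)
  }
  last <- first + as.integer(n_epochs) - 1L
  if (last > length(series$counts)) {
    stop("window not contained: series ends ",
         (last - length(series$counts)) * series$epoch_seconds / 60,
         " min before ", format(clock_time(end)), call. = FALSE)
  }
  epoch_slice(series, first, last)
}

#' Re-bin counts onto a coarser epoch grid
#'
#' Each output count is the sum of its constituent input counts, so total
#' activity is conserved.  `bin_seconds` must be an integer multiple of the
#' epoch length; a trailing partial bin is an error unless
#' `partial = "drop"`, in which case it is discarded with a message.
#'
#' @param series an [epoch_series()].
#' @param bin_seconds new epoch length in seconds.
#' @param partial policy for a trailing partial bin: `"error"` or `"drop"`.
#' @return an `epoch_series` with `epoch_seconds = bin_seconds`.
#' @export
bin_counts <- function(series, bin_seconds, partial = c("error", "drop")) {
  stopifnot(inherits(series, "epoch_series"))
  partial <- match.arg(partial)
  bin_seconds <- as.integer(bin_seconds)
  if (bin_seconds <= 0L || bin_seconds %% series$epoch_seconds != 0L) {
    stop("bin_seconds must be a positive multiple of epoch_seconds (",
         series$epoch_seconds, ")", call. = FALSE)
  }
  k <- bin_seconds %/% series$epoch_seconds
  if (k == 1L) return(series)
  n <- length(series$counts)
  n_full <- n %/% k
  if (n %% k != 0L) {
    if (partial == "error") {
      stop("series length ", n, " not divisible by bin ratio ", k,
           "; use partial = \"drop\" to discard the trailing partial bin",
           call. = FALSE)
    }
    message("bin_counts: dropping trailing partial bin of ", n %% k,
            " epoch(s)")
  }
  if (n_full < 1L) stop("series shorter than one bin", call. = FALSE)
  idx <- seq_len(n_full * k)
  binned <- as.numeric(rowsum(series$counts[idx],
                              rep(seq_len(n_full), each = k)))
  miss <- if (!is.null(series$missing)) {
    as.logical(rowsum(as.numeric(series$missing[idx]),
                      rep(seq_len(n_full), each = k)) > 0)
  }
  epoch_series(binned, series$start, bin_seconds, series$subject_id,
               series$meta, missing = miss)
}
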