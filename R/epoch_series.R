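#' Epoch-level activity-count series
#'
#' The universal input of the pipeline: a uniformly sampled sequence of
#' non-negative activity counts, one per epoch, with an absolute start time.
#' Sampling is strictly uniform; gaps must be represented through the
#' optional logical `missing` mask, never by dropping epochs.
#'
#' @param counts numeric vector of activity counts, all finite and >= 0.
#' @param start absolute start time of the first epoch: a `POSIXct`, or a
#'   string `"YYYY-MM-DD HH:MM:SS"` / `"YYYY-MM-DD HH:MM"` interpreted as a
#'   naive local clock (stored as UTC; the package does no time-zone
#'   arithmetic).
#' @param epoch_seconds positive integer epoch length in seconds
#'   (default 60, a typical collar-accelerometer setting).
#' @param subject_id subject label.
#' @param meta named list of free-form annotations.
#' @param missing optional logical mask, `TRUE` where the epoch is missing;
#'   masked counts are stored as recorded but flagged.
#' @return an object of class `"epoch_series"`.
#' @examples
#' s <- epoch_series(rpois(120, 5), "2018-06-01 09:00")
#' s
#' @export
epoch_series <- function(counts, start, epoch_seconds = 60L,
                         subject_id = "unknown", meta = list(),
                         missing = NULL) {
  counts <- as.numeric(counts)
  if (length(counts) < 1L) stop("counts must have length >= 1", call. = FALSE)
  if (any(!is.finite(counts))) stop("counts must all be finite", call. = FALSE)
  if (any(counts < 0)) stop("counts must all be >= 0", call. = FALSE)
  epoch_seconds <- as.integer(epoch_seconds)
  if (is.na(epoch_seconds) || epoch_seconds <= 0L) {
    stop("epoch_seconds must be a positive integer", call. = FALSE)
  }
  start <- as_start_time(start)
  if (!is.null(missing)) {
    missing <- as.logical(missing)
    if (length(missing) != length(counts) || anyNA(missing)) {
      stop("missing mask must be a logical vector aligned with counts",
           call. = FALSE)
    }
  }
  structure(
    list(subject_id = as.character(subject_id)[1L],
         start = start,
         epoch_seconds = epoch_seconds,
         counts = counts,
         missing = missing,
         meta = meta),
    class = "epoch_series")
}

as_start_time <- function(start) {
  if (inherits(start, "POSIXct")) {
    return(as.POSIXct(format(start, "%Y-%m-%d %H:%M:%S"), tz = "UTC"))
  }
  out <- as.POSIXct(start, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S",
                                   "%Y-%m-%d %H:%M"))
  if (is.na(out)) stop("cannot parse start time: ", start, call. = FALSE)
  out
}

#' @export
print.epoch_series <- function(x, ...) {
  cat("<epoch_series> subject", x$subject_id, "\n")
  cat("  start        ", format(x$start, "%Y-%m-%d %H:%M:%S"), "\n")
  cat("  epochs       ", length(x$counts), "x", x$epoch_seconds, "s (",
      format(round(length(x$counts) * x$epoch_seconds / 3600, 2)), "h )\n")
  cat("  total counts ", format(sum(x$counts)), "\n")
  if (!is.null(x$missing) && any(x$missing)) {
    cat("  missing      ", sum(x$missing), "epochs masked\n")
  }
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$counts)

#' @rdname epoch_series
#' @param x an `epoch_series`.
#' @param row.names,optional,... passed on conventionally; unused.
#' @export
as.data.frame.epoch_series <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  data.frame(
    timestamp = x$start + (seq_along(x$counts) - 1L) * x$epoch_seconds,
    count = x$counts)
}

# clock time (minutes since midnight, numeric) of each epoch start
epoch_clock_min <- function(series) {
  start_sec <- as.integer(format(series$start, "%H")) * 3600L +
    as.integer(format(series$start, "%M")) * 60L +
    as.integer(format(series$start, "%S"))
  sec <- (start_sec + (seq_along(series$counts) - 1L) *
            as.numeric(series$epoch_seconds)) %% 86400
  sec / 60
}

# sub-series of epochs [from, to] (1-based, inclusive), preserving identity
epoch_slice <- function(series, from, to) {
  stopifnot(from >= 1L, to <= length(series$counts), from <= to)
  epoch_series(series$counts[from:to],
               series$start + (from - 1L) * series$epoch_seconds,
               series$epoch_seconds, series$subject_id, series$meta,
               missing = if (!is.null(series$missing)) series$missing[from:to])
}

n_missing <- function(series) {
  if (is.null(series$missing)) 0L else sum(series$missing)
}
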