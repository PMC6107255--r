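#' Clock times within the 24-hour day
#'
#' Many operations in this package are anchored to wall-clock times (the
#' recording day starts at 09:00, the sleep window runs 19:00 to 06:30, and
#' so on).  A `clock_time` is a number of minutes since midnight, at minute
#' resolution, in the half-open range \[0, 1440).  Times may be given as
#' `"HH:MM"` strings or as numeric minutes; all exported functions accept
#' either form.
#'
#' @param x a character vector of `"HH:MM"` (or `"H:MM"`) strings, or a
#'   numeric vector of minutes since midnight.
#' @return an integer vector of minutes since midnight with class
#'   `"clock_time"`.
#' @examples
#' clock_time("19:00")
#' clock_time(c("06:30", "9:00"))
#' format(clock_time(1170))
#' @export
clock_time <- function(x) {
  if (inherits(x, "clock_time")) return(x)
  if (is.character(x)) {
    m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
    bad <- vapply(m, length, 1L) != 3L
    if (any(bad)) {
      stop("cannot parse clock time(s): ", paste(x[bad], collapse = ", "),
           " (expected \"HH:MM\")", call. = FALSE)
    }
    hh <- as.integer(vapply(m, `[`, "", 2L))
    mm <- as.integer(vapply(m, `[`, "", 3L))
    if (any(hh > 23L) || any(mm > 59L)) {
      stop("clock time out of range: must satisfy 00:00 <= t < 24:00",
           call. = FALSE)
    }
    mins <- hh * 60L + mm
  } else if (is.numeric(x)) {
    mins <- as.integer(round(x))
    if (any(mins < 0L) || any(mins >= 1440L)) {
      stop("clock time out of range: must satisfy 00:00 <= t < 24:00",
           call. = FALSE)
    }
  } else {
    stop("clock times must be \"HH:MM\" strings or numeric minutes",
         call. = FALSE)
  }
  structure(mins, class = "clock_time")
}

#' @export
format.clock_time <- function(x, ...) {
  sprintf("%02d:%02d", unclass(x) %/% 60L, unclass(x) %% 60L)
}

#' @export
print.clock_time <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# minutes-since-midnight as plain integer
as_clock_min <- function(x) as.integer(unclass(clock_time(x)))

# duration in minutes from a to b going forward on the clock, crossing
# midnight when b <= a; a full-day window is expressed as a == b + 1440 by
# callers that need it, so b == a here means 24 h.
clock_span_min <- function(a, b) {
  a <- as_clock_min(a); b <- as_clock_min(b)
  d <- (b - a) %% 1440L
  ifelse(d == 0L, 1440L, d)
}
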