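#' Nocturnal sleep window specification
#'
#' Marmosets hold a long sustained quiescence from early evening to early
#' morning; the default analysis window runs 19:00 to 06:30 (11.5 h) and is
#' the same fixed window for every subject, which standardises the period of
#' sleep analysed across animals with different settling times.
#'
#' @param start,end clock times bounding the nocturnal window.
#' @return a list with class `"sleep_window"`.
#' @export
sleep_window <- function(start = "19:00", end = "06:30") {
  w <- list(start = clock_time(start), end = clock_time(end))
  if (clock_span_min(w$start, w$end) <= 0) {
    stop("sleep window must have positive duration", call. = FALSE)
  }
  class(w) <- "sleep_window"
  w
}

#' @export
print.sleep_window <- function(x, ...) {
  cat("<sleep_window>", format(x$start), "->", format(x$end), "(",
      clock_span_min(x$start, x$end) / 60, "h )\n")
  invisible(x)
}

#' Classify epochs as mobile or immobile
#'
#' An epoch is immobile when its count is strictly below the immobility
#' threshold (default 1 count per epoch: marmosets show very little or no
#' activity during sleep, so any appreciable count marks movement).  A
#' threshold of 0 therefore labels every epoch mobile.
#'
#' @param window_series the clipped nocturnal [epoch_series()].
#' @param threshold immobility threshold in counts per epoch.
#' @return a character vector over `{"mobile","immobile"}` with class
#'   `"mobility_sequence"`; the raw counts and threshold travel along as
#'   attributes.
#' @export
classify_mobility <- function(window_series, threshold = 1) {
  stopifnot(inherits(window_series, "epoch_series"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("threshold must be a single non-negative number", call. = FALSE)
  }
  labels <- ifelse(window_series$counts < threshold, "immobile", "mobile")
  structure(labels, class = "mobility_sequence",
            counts = window_series$counts,
            epoch_seconds = window_series$epoch_seconds,
            threshold_used = threshold)
}

#' Score a mobility sequence into wake and sleep
#'
#' The default `"mobility"` policy relabels mobile epochs wake and immobile
#' epochs sleep.  The `"smoothed"` policy instead applies a centered
#' weighted moving sum of the raw counts and scores an epoch wake when that
#' sum reaches `wake_threshold`, which suppresses isolated movement spikes.
#'
#' @param mobility a [classify_mobility()] result.
#' @param policy `"mobility"` or `"smoothed"`.
#' @param weights odd-length kernel for the smoothed policy (default
#'   `c(1, 2, 4, 2, 1) / 10`, a 5-epoch centered kernel).
#' @param wake_threshold smoothed-count threshold for the smoothed policy.
#' @return a character vector over `{"wake","sleep"}`.
#' @export
score_sleep_wake <- function(mobility, policy = c("mobility", "smoothed"),
                             weights = c(1, 2, 4, 2, 1) / 10,
                             wake_threshold = 1) {
  stopifnot(inherits(mobility, "mobility_sequence"))
  policy <- match.arg(policy)
  if (policy == "mobility") {
    return(ifelse(unclass(mobility) == "mobile", "wake", "sleep"))
  }
  if (length(weights) %% 2L != 1L) {
    stop("smoothing kernel must have odd length", call. = FALSE)
  }
  counts <- attr(mobility, "counts")
  sm <- as.numeric(stats::filter(counts, weights, sides = 2))
  half <- (length(weights) - 1L) %/% 2L
  if (half > 0L && length(counts) > 2L * half) {
    # shrink the kernel near the edges rather than dropping epochs
    for (i in seq_len(half)) {
      w <- weights[(half - i + 2L):length(weights)]
      sm[i] <- sum(counts[1:(i + half)] * w)
      j <- length(counts) - i + 1L
      w <- weights[1:(length(weights) - half + i - 1L)]
      sm[j] <- sum(counts[(j - half):length(counts)] * w)
    }
  }
  ifelse(sm >= wake_threshold, "wake", "sleep")
}

#' Segment a binary label sequence into bouts
#'
#' A bout is a maximal run of identical labels; bouts partition the window
#' and adjacent bouts differ in state.
#'
#' @param labels character (or factor) vector of epoch labels.
#' @return a data frame with columns `state`, `start_epoch`, `length_epochs`.
#' @export
segment_bouts <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("empty label sequence", call. = FALSE)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  data.frame(state = r$values,
             start_epoch = ends - r$lengths + 1L,
             length_epochs = r$lengths,
             stringsAsFactors = FALSE)
}

#' Eight sleep-quality metrics for one night
#'
#' Clips the nocturnal window out of a recording, scores mobility and
#' wake/sleep, segments bouts, and computes in one pass the eight metrics
#' used to characterise sleep quality in the lesioned-marmoset work:
#'
#' * `pct_awake` -- % of window epochs scored wake;
#' * `n_wake_bouts` -- number of wake bouts;
#' * `mean_sleep_bout_len` -- mean sleep-bout length, minutes;
#' * `fragmentation_index` -- % mobile epochs plus % of immobile bouts no
#'   longer than one minute (the actiwatch-software convention; the exact
#'   composite is configurable via `fi_fun`);
#' * `n_immobile_phases` -- number of immobile bouts;
#' * `mean_immobility_len` -- mean immobile-bout length, minutes;
#' * `total_moving_time` -- mobile epochs expressed in minutes;
#' * `mean_activity` -- mean counts per epoch over the window.
#'
#' @param series an [epoch_series()] covering the window.
#' @param window a [sleep_window()].
#' @param threshold immobility threshold, counts per epoch.
#' @param policy,weights,wake_threshold passed to [score_sleep_wake()].
#' @param fi_fun alternative fragmentation-index function taking the
#'   mobility sequence and the immobile-bout table; `NULL` uses the default
#'   composite above.
#' @return a list of the eight metrics with class `"sleep_metrics"`.
#' @export
compute_sleep_metrics <- function(series, window = sleep_window(),
                                  threshold = 1,
                                  policy = c("mobility", "smoothed"),
                                  weights = c(1, 2, 4, 2, 1) / 10,
                                  wake_threshold = 1, fi_fun = NULL) {
  stopifnot(inherits(series, "epoch_series"), inherits(window, "sleep_window"))
  policy <- match.arg(policy)
  win <- clip_window(series, window$start, window$end)
  if (n_missing(win) > 0L) {
    message("compute_sleep_metrics: ignoring missing-mask on ",
            n_missing(win), " epoch(s)")
  }
  epoch_min <- win$epoch_seconds / 60
  mob <- classify_mobility(win, threshold)
  ws <- score_sleep_wake(mob, policy, weights, wake_threshold)
  ws_bouts <- segment_bouts(ws)
  mob_bouts <- segment_bouts(unclass(mob))
  n <- length(win$counts)

  sleep_b <- ws_bouts[ws_bouts$state == "sleep", , drop = FALSE]
  wake_b <- ws_bouts[ws_bouts$state == "wake", , drop = FALSE]
  imm_b <- mob_bouts[mob_bouts$state == "immobile", , drop = FALSE]
  pct_mobile <- 100 * sum(unclass(mob) == "mobile") / n

  fi <- if (!is.null(fi_fun)) {
    fi_fun(mob, imm_b)
  } else {
    short_imm <- if (nrow(imm_b)) {
      100 * sum(imm_b$length_epochs * epoch_min <= 1) / nrow(imm_b)
    } else 0
    pct_mobile + short_imm
  }

  structure(list(
    pct_awake = 100 * sum(ws == "wake") / n,
    n_wake_bouts = nrow(wake_b),
    mean_sleep_bout_len = if (nrow(sleep_b)) {
      mean(sleep_b$length_epochs) * epoch_min
    } else NA_real_,
    fragmentation_index = fi,
    n_immobile_phases = nrow(imm_b),
    mean_immobility_len = if (nrow(imm_b)) {
      mean(imm_b$length_epochs) * epoch_min
    } else NA_real_,
    total_moving_time = sum(unclass(mob) == "mobile") * epoch_min,
    mean_activity = mean(win$counts),
    window = window, threshold = threshold, n_epochs = n),
    class = "sleep_metrics")
}

#' @export
print.sleep_metrics <- function(x, digits = 3, ...) {
  cat("<sleep_metrics> window", format(x$window$start), "->",
      format(x$window$end), "(", x$n_epochs, "epochs )\n")
  m <- c("% awake" = x$pct_awake,
         "wake bouts" = x$n_wake_bouts,
         "mean sleep bout (min)" = x$mean_sleep_bout_len,
         "fragmentation index" = x$fragmentation_index,
         "immobile phases" = x$n_immobile_phases,
         "mean immobility (min)" = x$mean_immobility_len,
         "moving time (min)" = x$total_moving_time,
         "mean activity (counts/epoch)" = x$mean_activity)
  for (nm in names(m)) {
    cat(sprintf("  %-29s %s\n", nm, format(round(m[[nm]], digits))))
  }
  invisible(x)
}

#' @rdname compute_sleep_metrics
#' @param x a `sleep_metrics` object.
#' @param row.names,optional,... conventional arguments; unused.
#' @export
as.data.frame.sleep_metrics <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  data.frame(pct_awake = x$pct_awake, n_wake_bouts = x$n_wake_bouts,
             mean_sleep_bout_len = x$mean_sleep_bout_len,
             fragmentation_index = x$fragmentation_index,
             n_immobile_phases = x$n_immobile_phases,
             mean_immobility_len = x$mean_immobility_len,
             total_moving_time = x$total_moving_time,
             mean_activity = x$mean_activity)
}
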