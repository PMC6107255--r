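#' Parkinson's disease rating scale (PDRS) item registry
#'
#' The nonhuman-primate PDRS scores each item 0 (normal) to 3 (severe) and
#' sums them to a maximal disability score of 57.  The canonical `"pdrs57"`
#' registry ships 19 items x 3 = 57: the published item list names
#' "posture" twice and splits arm tremor and gross motor skills by side,
#' which would overshoot the printed maximum, so the duplicate is removed
#' and each bilateral pair is merged into a single item.  The registry is a
#' plain data frame, so alternative item compositions are drop-in.
#'
#' @param name registry name; only `"pdrs57"` is shipped.
#' @return a data frame with columns `item` and `max_score`, carrying
#'   attributes `scale_maximum` and `motor_items`.
#' @export
pdrs_registry <- function(name = "pdrs57") {
  if (!identical(name, "pdrs57")) {
    stop("unknown registry: ", name, call. = FALSE)
  }
  items <- c(
    "rest tremor", "action tremor", "tremor of the head",
    "arm tremor (bilateral)", "freezing", "locomotion",
    "fine motor skills right hand", "fine motor skills left hand",
    "bradykinesia right arm", "bradykinesia left arm", "posture",
    "hypokinesia", "balance", "startle response",
    "gross motor skills (bilateral)", "apathy", "vocalization",
    "drooling or frothing", "tongue/face/lips")
  motor <- setdiff(items, c("apathy", "vocalization", "drooling or frothing",
                            "startle response"))
  reg <- data.frame(item = items, max_score = 3L, stringsAsFactors = FALSE)
  structure(reg, scale_maximum = sum(reg$max_score), motor_items = motor,
            class = c("pdrs_registry", "data.frame"))
}

check_assessment <- function(scores, registry) {
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    stop("assessment must be a named vector of item scores", call. = FALSE)
  }
  unknown <- setdiff(names(scores), registry$item)
  if (length(unknown)) {
    stop("unknown item(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  maxima <- registry$max_score[match(names(scores), registry$item)]
  bad <- which(scores < 0 | scores > maxima | scores != round(scores))
  if (length(bad)) {
    stop("out-of-range score for item \"", names(scores)[bad[1L]],
         "\": ", scores[bad[1L]], " (allowed 0..", maxima[bad[1L]], ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' PDRS total and subscale scores
#'
#' `pdrs_total()` sums all item scores of an assessment; `pdrs_subscale()`
#' sums a subset of items (e.g. the motor items).  Scores are validated
#' against the registry: unknown items and out-of-range scores are errors
#' naming the offending item.
#'
#' @param scores named integer vector mapping item name to score.
#' @param registry a [pdrs_registry()].
#' @param items character vector of item names for the subscale.
#' @return the (sub)total score.
#' @examples
#' reg <- pdrs_registry()
#' full <- stats::setNames(rep(3L, nrow(reg)), reg$item)
#' pdrs_total(full, reg)   # 57
#' @export
pdrs_total <- function(scores, registry = pdrs_registry()) {
  check_assessment(scores, registry)
  sum(scores)
}

#' @rdname pdrs_total
#' @export
pdrs_subscale <- function(scores, registry = pdrs_registry(),
                          items = attr(registry, "motor_items")) {
  unknown <- setdiff(items, registry$item)
  if (length(unknown)) {
    stop("subscale item(s) not in registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  check_assessment(scores, registry)
  sum(scores[names(scores) %in% items])
}

#' Build an ORTBD trial table
#'
#' Object-retrieval-with-barrier-detour sessions are recorded as one row
#' per reach event.  Required columns: `trial` (integer), `open_side`
#' (`left`/`right`/`front`, constant within a trial), `latency_s`
#' (trial-level movement-initiation latency, repeated), `hand`
#' (`left`/`right`), `approach_side`, `touched_barrier` (logical),
#' `retrieved` (logical).  A trial with no attempt is one row with `hand`
#' `NA`.  At most one reach per trial may have `retrieved = TRUE` and it
#' must be the last.
#'
#' @param df data frame of reach events in session order.
#' @return the validated data frame with class `"ortbd_trials"`.
#' @export
ortbd_trials <- function(df) {
  need <- c("trial", "open_side", "latency_s", "hand", "approach_side",
            "touched_barrier", "retrieved")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!nrow(df)) stop("empty trial table", call. = FALSE)
  sides <- c("left", "right", "front")
  if (any(!df$open_side %in% sides)) {
    stop("open_side must be one of left/right/front", call. = FALSE)
  }
  attempted <- !is.na(df$hand)
  if (any(!df$hand[attempted] %in% c("left", "right"))) {
    stop("hand must be left or right", call. = FALSE)
  }
  if (any(!df$approach_side[attempted] %in% sides)) {
    stop("approach_side must be one of left/right/front", call. = FALSE)
  }
  if (any(df$latency_s[attempted] < 0, na.rm = TRUE)) {
    stop("latency_s must be >= 0", call. = FALSE)
  }
  for (tr in unique(df$trial)) {
    rows <- df[df$trial == tr, ]
    got <- which(rows$retrieved %in% TRUE)
    if (length(got) > 1L || (length(got) == 1L && got != nrow(rows))) {
      stop("trial ", tr, ": retrieval must be the single last reach",
           call. = FALSE)
    }
  }
  structure(df, class = c("ortbd_trials", "data.frame"))
}

#' Derive the ten ORTBD summary variables
#'
#' Computes, over an ordered session of trials: reaching disability (count
#' and % of reaches into the open side that do not retrieve), movement
#' initiation time (mean latency over attempted trials), execution (% of
#' trials retrieved on the first reach), correct (% of trials eventually
#' retrieved), reach number (mean reaches per attempted trial), hand
#' preference (first-reach hand proportions), hand bias (left vs right
#' counts over all reaches), awkward reach (reaches made with the hand
#' farthest from a lateral opening; front openings are never awkward),
#' perseverative response (reaches to the side that was open on the
#' previous trial but is closed now; the first trial offers no
#' opportunity), and barrier reach (reaches touching a closed side).
#'
#' @param trials an [ortbd_trials()] table (a plain data frame is
#'   validated first).
#' @return a list with class `"ortbd_summary"`.
#' @export
derive_ortbd <- function(trials) {
  if (!inherits(trials, "ortbd_trials")) trials <- ortbd_trials(trials)
  df <- as.data.frame(trials)
  trial_ids <- unique(df$trial)
  n_trials <- length(trial_ids)
  first_rows <- df[!duplicated(df$trial), ]
  attempted_trial <- tapply(!is.na(df$hand), df$trial, any)[
    as.character(trial_ids)]
  reaches <- df[!is.na(df$hand), , drop = FALSE]

  open_of <- stats::setNames(first_rows$open_side, first_rows$trial)
  prev_open <- stats::setNames(c(NA, open_of[-n_trials]), trial_ids)

  open_reach <- reaches$approach_side == reaches$open_side
  reaching_disability <- sum(open_reach & !reaches$retrieved)
  retrieved_by_trial <- tapply(df$retrieved %in% TRUE, df$trial, any)[
    as.character(trial_ids)]
  first_reach <- reaches[!duplicated(reaches$trial), , drop = FALSE]
  exec_ok <- first_reach$retrieved %in% TRUE
  execution_pct <- 100 * sum(exec_ok) / n_trials
  correct_pct <- 100 * sum(retrieved_by_trial) / n_trials

  persev <- reaches$approach_side == prev_open[as.character(reaches$trial)] &
    reaches$approach_side != reaches$open_side
  awkward <- reaches$open_side %in% c("left", "right") &
    reaches$hand == ifelse(reaches$open_side == "left", "right", "left")

  structure(list(
    n_trials = n_trials,
    n_attempted = sum(attempted_trial),
    reaching_disability = reaching_disability,
    reaching_disability_pct = if (sum(open_reach)) {
      100 * reaching_disability / sum(open_reach)
    } else 0,
    movement_initiation_time = if (any(attempted_trial)) {
      mean(first_rows$latency_s[attempted_trial])
    } else NA_real_,
    execution_pct = execution_pct,
    correct_pct = correct_pct,
    reach_number = if (any(attempted_trial)) {
      nrow(reaches) / sum(attempted_trial)
    } else NA_real_,
    hand_preference = prop_table(first_reach$hand),
    hand_bias = table(factor(reaches$hand, levels = c("left", "right"))),
    awkward_reach = sum(awkward),
    perseverative_response = sum(persev, na.rm = TRUE),
    barrier_reach = sum(reaches$touched_barrier %in% TRUE)),
    class = "ortbd_summary")
}

prop_table <- function(x) {
  tab <- table(factor(x, levels = c("left", "right")))
  if (sum(tab) == 0) tab * NA_real_ else tab / sum(tab)
}

#' @export
print.ortbd_summary <- function(x, digits = 2, ...) {
  cat("<ortbd_summary>", x$n_trials, "trials (", x$n_attempted,
      "attempted )\n")
  cat("  reaching disability   ", x$reaching_disability, "(",
      format(round(x$reaching_disability_pct, digits)), "% of open-side reaches )\n")
  cat("  movement initiation   ", format(round(x$movement_initiation_time,
                                               digits)), "s\n")
  cat("  execution / correct   ", format(round(x$execution_pct, digits)),
      "% /", format(round(x$correct_pct, digits)), "%\n")
  cat("  reach number          ", format(round(x$reach_number, digits)), "\n")
  cat("  hand bias (L/R)       ", paste(x$hand_bias, collapse = " / "), "\n")
  cat("  awkward reaches       ", x$awkward_reach, "\n")
  cat("  perseverative reaches ", x$perseverative_response, "\n")
  cat("  barrier reaches       ", x$barrier_reach, "\n")
  invisible(x)
}

#' Head-tremor frequency from oscillation counts
#'
#' Postural head tremor is quantified from video by counting bilateral
#' oscillations of the head about the midline over timed observation
#' windows.  Each window yields a frequency `count / duration`; the
#' estimate is their mean and SD across windows.
#'
#' @param sample data frame with columns `oscillation_count` and
#'   `duration_s` (one row per observation window).
#' @return a list with class `"tremor_estimate"`: `mean_hz`, `sd_hz`,
#'   `n_windows`, `per_window_hz`.
#' @examples
#' tremor_frequency(data.frame(oscillation_count = 43, duration_s = 10))
#' @export
tremor_frequency <- function(sample) {
  need <- c("oscillation_count", "duration_s")
  miss <- setdiff(need, names(sample))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!nrow(sample)) stop("need at least one observation window",
                          call. = FALSE)
  if (any(sample$duration_s <= 0)) {
    stop("window durations must be > 0", call. = FALSE)
  }
  if (any(sample$oscillation_count < 0)) {
    stop("oscillation counts must be >= 0", call. = FALSE)
  }
  hz <- sample$oscillation_count / sample$duration_s
  structure(list(mean_hz = mean(hz),
                 sd_hz = if (length(hz) > 1L) stats::sd(hz) else 0,
                 n_windows = length(hz), per_window_hz = hz),
            class = "tremor_estimate")
}

#' @export
print.tremor_estimate <- function(x, digits = 2, ...) {
  cat("<tremor_estimate>", format(round(x$mean_hz, digits)), "\u00b1",
      format(round(x$sd_hz, digits)), "Hz over", x$n_windows, "window(s)\n")
  invisible(x)
}
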