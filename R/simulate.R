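#' Configuration of the synthetic marmoset rest-activity generator
#'
#' The generator emulates the structure of healthy marmoset actigraphy: a
#' biphasic daytime profile (a plateau plus feeding-related peaks near
#' 10:00 and 16:00), an abrupt activity onset between 06:30 and 07:00, a
#' long nocturnal quiescence from 19:00, and brief nocturnal arousals.
#' Counts are gamma-mixed Poisson (overdispersed; `dispersion = 0` gives
#' the deterministic expected profile, small positive values approach pure
#' Poisson noise).  Nights are an alternating renewal process of sleep and
#' wake bouts with geometric lengths; wake-bout counts follow a nocturnal
#' intensity template that is elevated while settling after 19:00 and
#' before dawn and lowest after midnight, giving the record a well-defined
#' least-active period.
#'
#' @param epoch_seconds epoch length (s).
#' @param n_days number of simulated recording days.
#' @param day_start clock time the recording (and each day) starts.
#' @param start_date calendar date of the first epoch.
#' @param onset daytime activity onset clock time.
#' @param quiescence_start clock time activity ceases in the evening.
#' @param base_height daytime plateau, counts/epoch.
#' @param peak1_center,peak1_height,peak1_width_min first (morning)
#'   activity mode: center clock time, height (counts/epoch), Gaussian
#'   width (min).
#' @param peak2_center,peak2_height,peak2_width_min second (afternoon)
#'   mode.
#' @param ramp_min linear ramp length at the edges of the active window.
#' @param dispersion overdispersion of the gamma-mixed count noise
#'   (variance is `lambda * (1 + dispersion)`); 0 = deterministic.
#' @param arousal_rate expected nocturnal wake bouts per night; ignored
#'   when `sleep_bout_mean_min` is given.
#' @param sleep_bout_mean_min mean nocturnal sleep-bout length (min);
#'   overrides `arousal_rate`.
#' @param wake_bout_mean_min mean nocturnal wake-bout length (min).
#' @param burst_intensity mean counts/epoch of nocturnal wake bouts at
#'   template level 1.
#' @return a validated list with class `"activity_sim_config"`.
#' @export
activity_sim_config <- function(epoch_seconds = 60L, n_days = 3L,
                                day_start = "09:00",
                                start_date = "2018-06-01",
                                onset = "06:45",
                                quiescence_start = "19:00",
                                base_height = 50,
                                peak1_center = "10:00", peak1_height = 180,
                                peak1_width_min = 90,
                                peak2_center = "16:00", peak2_height = 140,
                                peak2_width_min = 75,
                                ramp_min = 10,
                                dispersion = 5,
                                arousal_rate = 25,
                                sleep_bout_mean_min = NULL,
                                wake_bout_mean_min = 2,
                                burst_intensity = 25) {
  cfg <- list(epoch_seconds = as.integer(epoch_seconds),
              n_days = as.integer(n_days),
              day_start = clock_time(day_start),
              start_date = start_date,
              onset = clock_time(onset),
              quiescence_start = clock_time(quiescence_start),
              base_height = base_height,
              peak1_center = clock_time(peak1_center),
              peak1_height = peak1_height,
              peak1_width_min = peak1_width_min,
              peak2_center = clock_time(peak2_center),
              peak2_height = peak2_height,
              peak2_width_min = peak2_width_min,
              ramp_min = ramp_min,
              dispersion = dispersion,
              arousal_rate = arousal_rate,
              sleep_bout_mean_min = sleep_bout_mean_min,
              wake_bout_mean_min = wake_bout_mean_min,
              burst_intensity = burst_intensity)
  with(cfg, {
    if (epoch_seconds <= 0L || n_days < 1L) {
      stop("epoch_seconds and n_days must be positive", call. = FALSE)
    }
    if (any(c(base_height, peak1_height, peak2_height, peak1_width_min,
              peak2_width_min, burst_intensity) <= 0)) {
      stop("heights, widths and intensities must be > 0", call. = FALSE)
    }
    if (dispersion < 0 || arousal_rate < 0 || wake_bout_mean_min <= 0) {
      stop("invalid noise or arousal parameters", call. = FALSE)
    }
    if (as_clock_min(onset) >= as_clock_min(peak1_center)) {
      stop("activity onset must precede the first activity mode",
           call. = FALSE)
    }
  })
  structure(cfg, class = "activity_sim_config")
}

#' Lesion (MPTP) effect configuration
#'
#' Transformations applied to the baseline generator to emulate the
#' parkinsonian phenotype: daytime amplitude reduction, more frequent
#' nocturnal arousals, shortened sleep bouts, a delayed onset of the most
#' active period (the whole diurnal waveform is translated later) and an
#' advanced least-active period (the nocturnal intensity template is
#' translated earlier).  The phase shifts translate deterministic profile
#' components only, keeping the effects orthogonal and individually
#' recoverable.  `hyperactive` adds intermittent high-intensity daytime
#' bursts emulating the tremor-burst phenotype seen in one animal.
#'
#' @param amplitude_scale daytime amplitude multiplier in (0, 1].
#' @param arousal_multiplier multiplier (>= 1) on the nocturnal arousal
#'   rate (implemented by shortening the mean sleep bout).
#' @param sleep_bout_scale multiplier in (0, 1] on the mean sleep-bout
#'   length.
#' @param m10_delay_min delay (min) of the diurnal waveform.
#' @param l5_advance_min advance (min) of the nocturnal intensity template.
#' @param hyperactive logical; add daytime high-intensity bursts.
#' @return a validated list with class `"mptp_effect_config"`.
#' @export
mptp_effect_config <- function(amplitude_scale = 1, arousal_multiplier = 1,
                               sleep_bout_scale = 1, m10_delay_min = 0,
                               l5_advance_min = 0, hyperactive = FALSE) {
  if (amplitude_scale <= 0 || amplitude_scale > 1) {
    stop("amplitude_scale must lie in (0, 1]", call. = FALSE)
  }
  if (arousal_multiplier < 1) {
    stop("arousal_multiplier must be >= 1", call. = FALSE)
  }
  if (sleep_bout_scale <= 0 || sleep_bout_scale > 1) {
    stop("sleep_bout_scale must lie in (0, 1]", call. = FALSE)
  }
  if (m10_delay_min < 0 || l5_advance_min < 0) {
    stop("phase shifts must be >= 0 minutes", call. = FALSE)
  }
  structure(list(amplitude_scale = amplitude_scale,
                 arousal_multiplier = arousal_multiplier,
                 sleep_bout_scale = sleep_bout_scale,
                 m10_delay_min = m10_delay_min,
                 l5_advance_min = l5_advance_min,
                 hyperactive = isTRUE(hyperactive)),
            class = "mptp_effect_config")
}

#' Dose-day (L-DOPA) simulation configuration
#'
#' An additive activity pulse on top of the baseline day: a smooth
#' unimodal curve rising from `onset_latency_min` after the dose to a
#' maximum at `peak_latency_min`, holding a sustained elevation, and
#' returning to zero `onset_latency_min + duration_min` after the dose --
#' the peak-then-sustained-elevation time course of an oral dopaminergic
#' dose.  The pulse height is
#' `(peak_height_multiplier - 1) * (mean pre-dose expected activity)`, so
#' a multiplier of 1 is a vehicle day: no pulse, and with the same seed the
#' series is identical to the undosed day.
#'
#' @param dose_time dose clock time.
#' @param onset_latency_min minutes from dose to response onset.
#' @param peak_latency_min minutes from dose to response peak.
#' @param duration_min response duration (onset to offset), minutes.
#' @param peak_height_multiplier pulse peak as a multiple of the pre-dose
#'   mean expected activity (1 = vehicle).
#' @param baseline_minutes pre-dose reference window.
#' @return a validated list with class `"dose_sim_config"`.
#' @export
dose_sim_config <- function(dose_time = "11:30", onset_latency_min = 30,
                            peak_latency_min = 70, duration_min = 240,
                            peak_height_multiplier = 40,
                            baseline_minutes = 150) {
  if (!(onset_latency_min < peak_latency_min &&
        peak_latency_min < onset_latency_min + duration_min)) {
    stop("require onset < peak < onset + duration", call. = FALSE)
  }
  if (peak_height_multiplier < 1) {
    stop("peak_height_multiplier must be >= 1", call. = FALSE)
  }
  structure(list(dose_time = clock_time(dose_time),
                 onset_latency_min = onset_latency_min,
                 peak_latency_min = peak_latency_min,
                 duration_min = duration_min,
                 peak_height_multiplier = peak_height_multiplier,
                 baseline_minutes = baseline_minutes),
            class = "dose_sim_config")
}

# gamma-mixed Poisson counts with mean lam and variance lam * (1 + phi);
# phi = 0 returns the deterministic mean profile
rcounts <- function(lam, phi) {
  if (phi <= 0) return(lam)
  out <- numeric(length(lam))
  pos <- lam > 0
  if (any(pos)) {
    mix <- stats::rgamma(sum(pos), shape = lam[pos] / phi, scale = phi)
    out[pos] <- stats::rpois(sum(pos), mix)
  }
  out
}

# nocturnal intensity template: strong settling restlessness until about
# 21:45 and strong pre-dawn restlessness from about 03:45, with a quiet
# core after midnight; u is the fraction of the (baseline-anchored) night
# elapsed.  The elevated shoulders bound the least-active period sharply,
# making its onset a well-defined per-night quantity (baseline onset near
# 22:00, as observed in healthy animals).
night_template <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  0.25 + 6 * stats::plogis(-(u - 0.234) / 0.064) +
    4.5 * stats::plogis((u - 0.745) / 0.07)
}

# signed minimal clock difference a - b in minutes, in [-720, 720)
clock_diff <- function(a, b) ((a - b + 720) %% 1440) - 720

# deterministic daytime expectation (counts/epoch) at clock minutes cl
daytime_lambda <- function(cl, cfg, effect) {
  d <- effect$m10_delay_min
  onset <- as_clock_min(cfg$onset) + d
  quiesc <- as_clock_min(cfg$quiescence_start) + d
  # active window evaluated on an unwrapped axis relative to onset
  rel <- (cl - onset) %% 1440
  span <- quiesc - onset
  active <- rel < span
  ramp <- pmin(1, pmin(rel, span - rel) / cfg$ramp_min)
  g <- function(center, h, w) {
    h * exp(-clock_diff(cl, as_clock_min(center) + d)^2 / (2 * w^2))
  }
  lam <- cfg$base_height +
    g(cfg$peak1_center, cfg$peak1_height, cfg$peak1_width_min) +
    g(cfg$peak2_center, cfg$peak2_height, cfg$peak2_width_min)
  ifelse(active, effect$amplitude_scale * lam * pmax(ramp, 0), 0)
}

no_effect <- function() mptp_effect_config()

#' Simulate a marmoset rest-activity record
#'
#' Draws a seeded synthetic [epoch_series()] under the baseline
#' configuration, optionally transformed by a lesion effect.  The output is
#' a pure function of `(config, effect, seed)`.
#'
#' @param config an [activity_sim_config()].
#' @param effect optional [mptp_effect_config()].
#' @param seed integer seed.
#' @param subject_id subject label for the series.
#' @return an [epoch_series()] of `n_days` recording days.
#' @examples
#' s <- simulate_activity(activity_sim_config(n_days = 2), seed = 1)
#' npcra_summary(s)
#' @export
simulate_activity <- function(config = activity_sim_config(), effect = NULL,
                              seed = 1L, subject_id = "sim") {
  stopifnot(inherits(config, "activity_sim_config"))
  if (is.null(effect)) effect <- no_effect()
  stopifnot(inherits(effect, "mptp_effect_config"))
  with_seed(seed, simulate_activity_impl(config, effect, subject_id))
}

simulate_activity_impl <- function(cfg, effect, subject_id) {
  epm <- cfg$epoch_seconds / 60
  n <- as.integer(cfg$n_days * 86400 / cfg$epoch_seconds)
  start <- as_start_time(paste(cfg$start_date, format(cfg$day_start)))
  cl <- (as_clock_min(cfg$day_start) + (seq_len(n) - 1L) * epm) %% 1440

  lam <- daytime_lambda(cl, cfg, effect)
  if (effect$hyperactive) lam <- lam + hyper_bursts(cl, cfg, effect)
  counts <- rcounts(lam, cfg$dispersion)

  active <- lam > 0
  night_len <- 1440 - (as_clock_min(cfg$quiescence_start) -
                         as_clock_min(cfg$onset))
  L <- if (!is.null(cfg$sleep_bout_mean_min)) {
    cfg$sleep_bout_mean_min
  } else if (cfg$arousal_rate > 0) {
    max(night_len / cfg$arousal_rate - cfg$wake_bout_mean_min, 1)
  } else Inf
  L <- max(L * effect$sleep_bout_scale / effect$arousal_multiplier, 1)
  if (is.finite(L)) {
    r <- rle(active)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (b in which(!r$values)) {
      idx <- starts[b]:ends[b]
      st <- night_states(length(idx), L / epm,
                         max(cfg$wake_bout_mean_min / epm, 1))
      wake <- idx[st]
      if (length(wake)) {
        u <- ((cl[wake] - as_clock_min(cfg$quiescence_start) +
                 effect$l5_advance_min) %% 1440) / night_len
        mu <- cfg$burst_intensity * night_template(u)
        counts[wake] <- counts[wake] +
          if (cfg$dispersion > 0) rcounts(mu, cfg$dispersion) else mu
      }
    }
  }
  epoch_series(counts, start, cfg$epoch_seconds, subject_id,
               meta = list(generator = "simulate_activity"))
}

# alternating sleep/wake renewal; TRUE = wake epoch
night_states <- function(n_epochs, sleep_mean, wake_mean) {
  out <- logical(n_epochs)
  i <- 1L
  awake <- FALSE
  while (i <= n_epochs) {
    len <- 1L + stats::rgeom(1L, 1 / max(if (awake) wake_mean else sleep_mean,
                                         1))
    j <- min(i + len - 1L, n_epochs)
    out[i:j] <- awake
    awake <- !awake
    i <- j + 1L
  }
  out
}

# intermittent high-intensity daytime bursts (tremor-burst phenotype)
hyper_bursts <- function(cl, cfg, effect, rate_per_day = 6,
                         intensity = 800, mean_len_min = 10) {
  lam <- numeric(length(cl))
  d <- effect$m10_delay_min
  onset <- as_clock_min(cfg$onset) + d
  quiesc <- as_clock_min(cfg$quiescence_start) + d
  active_idx <- which((cl - onset) %% 1440 < (quiesc - onset))
  n_b <- stats::rpois(1L, rate_per_day * cfg$n_days)
  if (n_b > 0 && length(active_idx)) {
    starts <- sort(sample(active_idx, n_b, replace = TRUE))
    epm <- cfg$epoch_seconds / 60
    for (s in starts) {
      len <- 1L + stats::rgeom(1L, 1 / max(mean_len_min / epm, 1))
      lam[s:min(s + len - 1L, length(cl))] <- intensity
    }
  }
  lam
}

#' Simulate a dose (L-DOPA or vehicle) recording day
#'
#' One baseline day plus the additive post-dose pulse of a
#' [dose_sim_config()].  With `peak_height_multiplier = 1` (vehicle) the
#' series is identical to the undosed day under the same seed.
#'
#' @param config an [activity_sim_config()] (its `n_days` is forced to 1).
#' @param dose a [dose_sim_config()].
#' @param effect optional [mptp_effect_config()] (dosed animals are
#'   typically lesioned).
#' @param seed integer seed.
#' @param subject_id subject label.
#' @return an [epoch_series()] of one recording day; the absolute dose time
#'   is stored in `meta$dose_time`.
#' @export
simulate_dose_day <- function(config = activity_sim_config(),
                              dose = dose_sim_config(), effect = NULL,
                              seed = 1L, subject_id = "sim") {
  stopifnot(inherits(config, "activity_sim_config"),
            inherits(dose, "dose_sim_config"))
  if (is.null(effect)) effect <- no_effect()
  cfg <- config
  cfg$n_days <- 1L
  epm <- cfg$epoch_seconds / 60
  dose_off <- (as_clock_min(dose$dose_time) - as_clock_min(cfg$day_start)) %%
    1440
  if (dose_off < dose$baseline_minutes) {
    stop("dose falls before the baseline window of the recorded day",
         call. = FALSE)
  }
  if (dose_off + dose$onset_latency_min + dose$duration_min > 1440) {
    stop("dose response extends past the recorded day", call. = FALSE)
  }
  ser <- with_seed(seed, {
    base <- simulate_activity_impl(cfg, effect, subject_id)
    mins <- (seq_along(base$counts) - 1L) * epm
    pre <- mins >= dose_off - dose$baseline_minutes & mins < dose_off
    ref <- mean(daytime_lambda((as_clock_min(cfg$day_start) + mins[pre]) %%
                                 1440, cfg, effect))
    height <- (dose$peak_height_multiplier - 1) * ref
    s_rel <- mins - dose_off - dose$onset_latency_min
    shape <- pulse_shape(s_rel, dose$peak_latency_min - dose$onset_latency_min,
                         dose$duration_min)
    extra <- if (height > 0) {
      rcounts(height * shape, cfg$dispersion)
    } else numeric(length(shape))
    base$counts <- base$counts + extra
    base
  })
  ser$meta$dose_time <- format(ser$start + dose_off * 60,
                               "%Y-%m-%d %H:%M:%S")
  ser$meta$generator <- "simulate_dose_day"
  ser
}

# smooth unimodal pulse over [0, D] (s measured from response onset):
# a sustained plateau (half-cosine rise to the peak time, level hold,
# half-cosine fall over the last fall_min minutes) carrying a Gaussian
# peak at sp, so the maximum is exactly 1 at sp.  Mirrors the reported
# response: activity rises, peaks, stays elevated and subsides by the end.
pulse_shape <- function(s, sp, D, plateau = 0.7, peak_sigma = 15,
                        fall_min = 60) {
  base <- numeric(length(s))
  s2 <- D - fall_min
  rise <- s >= 0 & s <= sp
  hold <- s > sp & s <= s2
  fall <- s > s2 & s <= D
  base[rise] <- plateau * 0.5 * (1 - cos(pi * s[rise] / sp))
  base[hold] <- plateau
  base[fall] <- plateau * 0.5 * (1 + cos(pi * (s[fall] - s2) / fall_min))
  bump <- ifelse(s >= 0 & s <= D,
                 (1 - plateau) * exp(-(s - sp)^2 / (2 * peak_sigma^2)), 0)
  base + bump
}

#' Simulate head-tremor observation windows
#'
#' Draws per-window oscillation counts around `frequency_hz * duration_s`
#' with Gaussian jitter on the per-window frequency.
#'
#' @param frequency_hz true mean oscillation frequency (> 0).
#' @param jitter_sd SD of the per-window frequency (Hz).
#' @param duration_s window duration (s).
#' @param n_windows number of observation windows.
#' @param seed integer seed.
#' @return a data frame with columns `oscillation_count`, `duration_s`,
#'   suitable for [tremor_frequency()].
#' @export
simulate_tremor <- function(frequency_hz, jitter_sd = 0.5, duration_s = 10,
                            n_windows = 20, seed = 1L) {
  if (frequency_hz <= 0) stop("frequency must be > 0", call. = FALSE)
  if (jitter_sd < 0 || duration_s <= 0 || n_windows < 1) {
    stop("invalid tremor simulation parameters", call. = FALSE)
  }
  with_seed(seed, {
    f <- pmax(stats::rnorm(n_windows, frequency_hz, jitter_sd), 0)
    data.frame(oscillation_count = round(f * duration_s),
               duration_s = duration_s)
  })
}

#' ORTBD session simulation configuration
#'
#' @param n_trials_per_day,n_days session layout (20 trials on each of 3
#'   consecutive days by default).
#' @param p_success probability any given reach retrieves the reward.
#' @param p_barrier probability a failed reach goes to a closed side
#'   (touching the barrier).
#' @param p_perseveration probability a failed reach repeats the previous
#'   trial's (now closed) open side.
#' @param p_left_hand hand-preference probability of reaching left-handed.
#' @param p_awkward probability of reaching with the hand farthest from a
#'   lateral opening.
#' @param latency_meanlog,latency_sdlog log-normal parameters of the
#'   movement-initiation latency (s).
#' @param max_reaches reach cap per trial; a trial failing this many
#'   reaches ends unretrieved.
#' @return a validated list with class `"ortbd_sim_config"`.
#' @export
ortbd_sim_config <- function(n_trials_per_day = 20L, n_days = 3L,
                             p_success = 0.9, p_barrier = 0.15,
                             p_perseveration = 0.1, p_left_hand = 0.5,
                             p_awkward = 0.05, latency_meanlog = log(1.5),
                             latency_sdlog = 0.4, max_reaches = 6L) {
  probs <- c(p_success, p_barrier, p_perseveration, p_left_hand, p_awkward)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_trials_per_day < 1L || n_days < 1L || max_reaches < 1L) {
    stop("invalid session layout", call. = FALSE)
  }
  structure(list(n_trials_per_day = as.integer(n_trials_per_day),
                 n_days = as.integer(n_days), p_success = p_success,
                 p_barrier = p_barrier, p_perseveration = p_perseveration,
                 p_left_hand = p_left_hand, p_awkward = p_awkward,
                 latency_meanlog = latency_meanlog,
                 latency_sdlog = latency_sdlog,
                 max_reaches = as.integer(max_reaches)),
            class = "ortbd_sim_config")
}

#' Simulate an ORTBD session
#'
#' Open sides are drawn uniformly over left/right/front; each reach
#' retrieves with probability `p_success`, and failed reaches go to the
#' previously open side (perseveration), a closed side (barrier touch) or
#' into the open side without retrieval, per the configured probabilities.
#' Retrieval, when it happens, is the last reach of its trial.
#'
#' @param config an [ortbd_sim_config()].
#' @param seed integer seed.
#' @return an [ortbd_trials()] table.
#' @export
simulate_ortbd <- function(config = ortbd_sim_config(), seed = 1L) {
  stopifnot(inherits(config, "ortbd_sim_config"))
  with_seed(seed, {
    sides <- c("left", "right", "front")
    n_trials <- config$n_trials_per_day * config$n_days
    rows <- vector("list", n_trials)
    prev_open <- NA_character_
    for (tr in seq_len(n_trials)) {
      open <- sample(sides, 1L)
      latency <- stats::rlnorm(1L, config$latency_meanlog,
                               config$latency_sdlog)
      reaches <- list()
      for (k in seq_len(config$max_reaches)) {
        success <- stats::runif(1L) < config$p_success
        if (success) {
          approach <- open
          barrier <- FALSE
        } else if (!is.na(prev_open) && prev_open != open &&
                   stats::runif(1L) < config$p_perseveration) {
          approach <- prev_open
          barrier <- TRUE
        } else if (stats::runif(1L) < config$p_barrier) {
          approach <- sample(setdiff(sides, open), 1L)
          barrier <- TRUE
        } else {
          approach <- open
          barrier <- FALSE
        }
        far_hand <- if (open == "left") "right" else "left"
        hand <- if (open %in% c("left", "right") &&
                    stats::runif(1L) < config$p_awkward) {
          far_hand
        } else if (stats::runif(1L) < config$p_left_hand) "left" else "right"
        reaches[[k]] <- data.frame(trial = tr, open_side = open,
                                   latency_s = latency, hand = hand,
                                   approach_side = approach,
                                   touched_barrier = barrier,
                                   retrieved = success)
        if (success) break
      }
      rows[[tr]] <- do.call(rbind, reaches)
      prev_open <- open
    }
    ortbd_trials(do.call(rbind, rows))
  })
}

#' Simulate a PDRS assessment
#'
#' Item scores are binomial over 0..3 with a severity-specific success
#' probability chosen so the expected total matches the preset: 0
#' (healthy), 43 (acute, one month post-lesion) or 29 (chronic, six
#' months, after partial stabilisation).
#'
#' @param severity `"healthy"`, `"acute"` or `"chronic"`.
#' @param registry a [pdrs_registry()].
#' @param seed integer seed.
#' @return a named integer vector of item scores.
#' @export
simulate_pdrs <- function(severity = c("healthy", "acute", "chronic"),
                          registry = pdrs_registry(), seed = 1L) {
  severity <- match.arg(severity)
  target <- c(healthy = 0, acute = 43, chronic = 29)[[severity]]
  p <- target / attr(registry, "scale_maximum")
  with_seed(seed, {
    stats::setNames(stats::rbinom(nrow(registry), registry$max_score, p),
                    registry$item)
  })
}

# evaluate expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
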