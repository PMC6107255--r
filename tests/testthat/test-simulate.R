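test_that("generators are pure functions of configuration and seed", {
  cfg <- activity_sim_config(n_days = 2)
  a <- simulate_activity(cfg, seed = 3)
  b <- simulate_activity(cfg, seed = 3)
  expect_identical(a$counts, b$counts)
  expect_false(identical(a$counts, simulate_activity(cfg, seed = 4)$counts))

  expect_identical(simulate_ortbd(seed = 2), simulate_ortbd(seed = 2))
  expect_identical(simulate_tremor(4.3, seed = 2),
                   simulate_tremor(4.3, seed = 2))
  expect_identical(simulate_pdrs("acute", seed = 2),
                   simulate_pdrs("acute", seed = 2))
})

test_that("the noiseless limit reproduces the deterministic profile", {
  cfg <- activity_sim_config(n_days = 1, dispersion = 0, arousal_rate = 0)
  s <- simulate_activity(cfg, seed = 1)
  expect_identical(s$counts, simulate_activity(cfg, seed = 99)$counts)
  night <- clip_window(s, "19:30", "06:00")
  expect_true(all(night$counts == 0))
  pks <- unclass(detect_peaks(hourly_profile(s), smooth_bins = 1))
  expect_true(any(abs(pks - 600) <= 60))
  expect_true(any(abs(pks - 960) <= 60))
})

test_that("simulated nights have near-zero counts outside arousals", {
  s <- simulate_activity(activity_sim_config(n_days = 3), seed = 8)
  night <- clip_window(s, "22:00", "03:00")
  expect_gt(mean(night$counts == 0), 0.8)
})

test_that("dose-day pulses obey their closed-form shape", {
  cfg <- activity_sim_config(n_days = 1, dispersion = 0, arousal_rate = 0)
  dose <- dose_sim_config()
  s <- simulate_dose_day(cfg, dose, seed = 1)
  base <- simulate_activity(cfg, seed = 1)
  extra <- s$counts - base$counts
  # peak exactly at the configured 70 min post-dose
  dose_epoch <- 151
  expect_equal(which.max(extra) - dose_epoch, 70)
  # additive pulse AUC matches the numeric integral of the shape curve
  mult <- dose$peak_height_multiplier
  shape_int <- stats::integrate(function(s_min) {
    marmact:::pulse_shape(s_min, 40, 240)
  }, 0, 240)$value
  ref <- sum(extra) / (mult - 1) / shape_int
  # ref is the pre-dose mean expected activity; cross-check it directly
  pre <- base$counts[(dose_epoch - 150):(dose_epoch - 1)]
  expect_lt(abs(ref - mean(pre)) / mean(pre), 0.01)

  # vehicle day: multiplier 1 leaves the series untouched
  veh <- simulate_dose_day(cfg, dose_sim_config(peak_height_multiplier = 1),
                           seed = 1)
  expect_identical(veh$counts, base$counts)
})

test_that("simulated tremor windows hit their configured rate", {
  exact <- simulate_tremor(4.3, jitter_sd = 0, duration_s = 10,
                           n_windows = 5, seed = 1)
  expect_true(all(exact$oscillation_count == 43))

  est <- tremor_frequency(simulate_tremor(4.3, jitter_sd = 0.5,
                                          n_windows = 20, seed = 1))
  expect_lt(abs(est$mean_hz - 4.3), 0.2)
  expect_error(simulate_tremor(0), "> 0")
})

test_that("ORTBD simulation recovers the configured success rate", {
  cfg <- ortbd_sim_config(n_trials_per_day = 200, n_days = 3,
                          p_success = 0.6)
  o <- derive_ortbd(simulate_ortbd(cfg, seed = 3))
  se <- sqrt(0.6 * 0.4 / 600) * 100
  expect_lt(abs(o$execution_pct - 60), 3 * se)

  perfect <- derive_ortbd(simulate_ortbd(ortbd_sim_config(p_success = 1),
                                         seed = 1))
  expect_equal(perfect$execution_pct, 100)
  expect_error(ortbd_sim_config(p_success = 1.2), "probabilities")
})

test_that("PDRS presets hit their expected totals and ordering", {
  reg <- pdrs_registry()
  expect_equal(pdrs_total(simulate_pdrs("healthy", reg, seed = 1), reg), 0L)
  acute <- vapply(1:400, function(i) {
    pdrs_total(simulate_pdrs("acute", reg, seed = i), reg)
  }, numeric(1))
  chronic <- vapply(1:400, function(i) {
    pdrs_total(simulate_pdrs("chronic", reg, seed = i), reg)
  }, numeric(1))
  expect_lt(abs(mean(acute) - 43), 2)
  expect_lt(abs(mean(chronic) - 29), 2)
  expect_lt(mean(chronic), mean(acute))
  expect_true(all(acute <= 57))
})

test_that("presets load, validate, and drive the generators", {
  expect_setequal(available_presets(),
                  c("baseline-marmoset", "mptp-acute", "mptp-hyperactive",
                    "ldopa-day", "vehicle-day"))
  p <- load_preset("mptp-acute")
  expect_s3_class(p$activity, "activity_sim_config")
  expect_equal(p$effect$amplitude_scale, 0.5)
  expect_null(p$dose)
  expect_error(load_preset("nonexistent"), "unknown preset")

  s <- simulate_preset("baseline-marmoset", seed = 1, n_days = 2)
  expect_length(segment_days(s), 2L)
  d <- simulate_preset("ldopa-day", seed = 1)
  expect_match(d$meta$dose_time, "11:30")
})

test_that("invalid generator configurations are refused", {
  expect_error(activity_sim_config(peak1_height = -1), "> 0")
  expect_error(activity_sim_config(onset = "11:00"), "precede")
  expect_error(mptp_effect_config(amplitude_scale = 0), "\\(0, 1\\]")
  expect_error(mptp_effect_config(arousal_multiplier = 0.5), ">= 1")
  expect_error(dose_sim_config(peak_latency_min = 20), "onset < peak")
})
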