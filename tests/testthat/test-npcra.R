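test_that("hourly profiles place and conserve counts", {
  s <- make_series(48)
  p <- hourly_profile(s)
  expect_equal(dim(unclass(p)), c(2L, 24L))
  expect_true(all(unclass(p) == 60))

  counts <- rep(0, 1440)
  counts[91] <- 10          # 10:30 on a day starting 09:00
  one <- epoch_series(counts, "2018-06-01 09:00")
  p1 <- hourly_profile(one)
  expect_equal(sum(unclass(p1)), 10)
  expect_equal(unclass(p1)[1, 2], 10)  # the 10:00 hourly bin

  expect_error(hourly_profile(make_series(23)), "insufficient span")
  masked <- epoch_series(rep(1, 1440), "2018-06-01 09:00",
                         missing = c(TRUE, rep(FALSE, 1439)))
  expect_error(hourly_profile(masked), "complete data")
})

test_that("IS is 1 for identical days, 0 for complementary days, and matches
          the literal formula", {
  one_day <- c(rpois(12, 50), rpois(12, 3))
  rep3 <- matrix(rep(one_day, 3), nrow = 3, byrow = TRUE)
  expect_equal(interdaily_stability(rep3), 1, tolerance = 1e-12)

  # two days whose hourly means are constant: between-hour variance vanishes
  d1 <- c(rep(0, 12), rep(10, 12))
  comp <- rbind(d1, 10 - d1)
  expect_equal(interdaily_stability(comp), 0, tolerance = 1e-12)

  set.seed(31)
  for (i in 1:5) {
    m <- matrix(rgamma(240, 2, 0.1), nrow = 10)
    expect_equal(interdaily_stability(m), oracle_is(m), tolerance = 1e-12)
    expect_equal(intradaily_variability(m), oracle_iv(m), tolerance = 1e-12)
  }

  expect_error(interdaily_stability(matrix(5, 3, 24)), "constant")
  expect_error(interdaily_stability(matrix(1, 1, 24)), "2 complete days")
})

test_that("IV hits its closed forms and white-noise expectation", {
  alt <- matrix(rep(c(0, 1), 36), nrow = 3, byrow = TRUE)
  expect_equal(intradaily_variability(alt), 4, tolerance = 1e-12)

  # pure 24-h cosine sampled hourly: IV -> 2 * (1 - cos(2*pi/24))
  hours <- 0:(24 * 30 - 1)
  cosine <- matrix(10 + cos(2 * pi * hours / 24), ncol = 24, byrow = TRUE)
  expect_equal(intradaily_variability(cosine), 2 * (1 - cos(2 * pi / 24)),
               tolerance = 5e-3)

  set.seed(99)
  wn <- matrix(rnorm(240, 100, 15), nrow = 10)
  expect_gt(intradaily_variability(wn), 1.8)
  expect_lt(intradaily_variability(wn), 2.2)

  expect_error(intradaily_variability(matrix(1, 1, 24)), "25 hourly")
})

test_that("IS and IV are invariant under positive rescaling of counts", {
  set.seed(12)
  m <- matrix(rgamma(240, 2, 0.05), nrow = 10)
  expect_equal(interdaily_stability(m * 7.3), interdaily_stability(m),
               tolerance = 1e-12)
  expect_equal(intradaily_variability(m * 7.3), intradaily_variability(m),
               tolerance = 1e-12)
})

test_that("added noise of increasing variance lowers expected IS", {
  template <- c(rep(5, 6), rep(120, 12), rep(5, 6))
  mean_is <- vapply(c(1, 10, 40), function(sdev) {
    set.seed(2024)
    mean(vapply(1:10, function(i) {
      m <- matrix(rep(template, 8), nrow = 8, byrow = TRUE) +
        matrix(abs(rnorm(192, 0, sdev)), nrow = 8)
      interdaily_stability(m)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_is) < 0))
})

test_that("extreme_window matches block constructions and symmetry", {
  counts <- rep(0, 24); counts[3:12] <- 100   # flat 10-h block
  day <- hourly_day(counts)
  most <- extreme_window(day, 10, "most")
  expect_equal(most$mean_activity, 100)
  expect_equal(format(most$onset), "02:00")
  least <- extreme_window(day, 5, "least")
  expect_equal(least$mean_activity, 0)

  # cosine peaking at 12:00: the most-active 10 h is centered on the peak
  cos_day <- hourly_day(10 + cos(2 * pi * ((0:23) - 12) / 24))
  expect_equal(format(extreme_window(cos_day, 10, "most")$onset), "07:00")

  expect_error(extreme_window(day, 24, "most"), "between 0 and 24")
})

test_that("extreme_window equals the exhaustive oracle on random days", {
  set.seed(7)
  for (i in 1:50) {
    counts <- rgamma(24, 1.5, 0.01)
    day <- hourly_day(counts)
    for (mode in c("least", "most")) {
      got <- extreme_window(day, 5, mode)
      want <- brute_extreme(counts, 3600, 5, mode)
      expect_equal(got$mean_activity, want$mean_activity)
      expect_equal(unclass(got$onset), want$offset_min %% 1440)
    }
  }
  # finer grids on minute epochs
  set.seed(8)
  for (i in 1:5) {
    counts <- rpois(1440, 2)
    day <- epoch_series(counts, "2018-06-01 09:00")
    for (step in c(15, 30, 60)) {
      got <- extreme_window(day, 5, "least", step_minutes = step)
      want <- brute_extreme(counts, 60, 5, "least", step_minutes = step)
      expect_equal(got$mean_activity, want$mean_activity)
      expect_equal(unclass(got$onset), (540 + want$offset_min) %% 1440)
    }
  }
})

test_that("relative amplitude reproduces its formula and bounds", {
  expect_equal(relative_amplitude(6169, 10), 6159 / 6179)
  expect_lt(abs(relative_amplitude(6169, 10) - 0.99), 0.01)
  expect_equal(relative_amplitude(500, 0), 1)
  expect_equal(relative_amplitude(500, 500), 0)
  expect_error(relative_amplitude(0, 0), "no activity")
  expect_error(relative_amplitude(5, 10), "m10 >= l5")
  expect_equal(rhythm_amplitude(6169, 10), 6159)
})

test_that("npcra_summary aggregates per-day statistics coherently", {
  one_day <- c(rpois(12, 80), rpois(12, 2))
  s <- epoch_series(rep(rep(one_day, each = 60) / 60, 3),
                    "2018-06-01 09:00")
  res <- npcra_summary(s)
  expect_equal(res$is, 1, tolerance = 1e-12)
  expect_equal(res$summary$l5[["sd"]], 0)
  expect_equal(res$summary$m10[["sd"]], 0)
  expect_equal(res$summary$amplitude[["sd"]], 0)
  # amplitude mean = mean(M10) - mean(L5) by linearity
  expect_equal(res$summary$amplitude[["mean"]],
               res$summary$m10[["mean"]] - res$summary$l5[["mean"]])
  expect_true(all(res$per_day$relative_amplitude >= 0 &
                    res$per_day$relative_amplitude <= 1))
  expect_true(all(res$per_day$amplitude >= 0))
  expect_error(npcra_summary(make_series(24)), "at least 2")
})
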