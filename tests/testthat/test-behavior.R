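test_that("the canonical PDRS registry sums to the scale maximum", {
  reg <- pdrs_registry()
  expect_equal(attr(reg, "scale_maximum"), 57L)
  expect_equal(sum(reg$max_score), 57L)
  expect_false(anyDuplicated(reg$item) > 0)

  zero <- stats::setNames(rep(0L, nrow(reg)), reg$item)
  expect_equal(pdrs_total(zero, reg), 0L)
  full <- stats::setNames(reg$max_score, reg$item)
  expect_equal(pdrs_total(full, reg), 57L)

  five <- zero
  five[c(1, 3, 5, 7, 9)] <- 2L
  expect_equal(pdrs_total(five, reg), 10L)

  expect_error(pdrs_total(c(gait = 2), reg), "unknown item")
  bad <- zero; bad[["freezing"]] <- 4L
  expect_error(pdrs_total(bad, reg), "freezing")
  expect_error(pdrs_registry("updrs"), "unknown registry")
})

test_that("subscales are additive over disjoint item sets", {
  reg <- pdrs_registry()
  set.seed(10)
  scores <- stats::setNames(sample(0:3, nrow(reg), replace = TRUE), reg$item)
  expect_equal(pdrs_subscale(scores, reg, reg$item), pdrs_total(scores, reg))
  expect_equal(pdrs_subscale(scores, reg, character(0)), 0L)

  tremor_items <- grep("tremor", reg$item, value = TRUE)
  rest <- setdiff(reg$item, tremor_items)
  expect_equal(pdrs_subscale(scores, reg, tremor_items) +
                 pdrs_subscale(scores, reg, rest),
               pdrs_total(scores, reg))
  expect_equal(pdrs_subscale(scores, reg, tremor_items),
               sum(scores[tremor_items]))
  # permutation invariance
  expect_equal(pdrs_total(scores[sample(names(scores))], reg),
               pdrs_total(scores, reg))
  expect_error(pdrs_subscale(scores, reg, "gait"), "not in registry")
})

perfect_session <- function(n = 20) {
  ortbd_trials(data.frame(
    trial = seq_len(n),
    open_side = rep(c("left", "right", "front"), length.out = n),
    latency_s = 1.5,
    hand = ifelse(rep(c("left", "right", "front"), length.out = n) ==
                    "right", "right", "left"),
    approach_side = rep(c("left", "right", "front"), length.out = n),
    touched_barrier = FALSE,
    retrieved = TRUE))
}

test_that("a perfect session scores perfectly", {
  o <- derive_ortbd(perfect_session())
  expect_equal(o$execution_pct, 100)
  expect_equal(o$correct_pct, 100)
  expect_equal(o$reach_number, 1)
  expect_equal(o$reaching_disability, 0L)
  expect_equal(o$barrier_reach, 0L)
  expect_equal(o$awkward_reach, 0L)
  expect_equal(o$movement_initiation_time, 1.5)
})

test_that("a hand-built impaired session is scored per the ten definitions", {
  df <- rbind(
    # trial 1 (open left): first-reach success
    data.frame(trial = 1, open_side = "left", latency_s = 2, hand = "left",
               approach_side = "left", touched_barrier = FALSE,
               retrieved = TRUE),
    # trial 2 (open right): barrier touch then success on second reach
    data.frame(trial = 2, open_side = "right", latency_s = 4,
               hand = "right", approach_side = "front",
               touched_barrier = TRUE, retrieved = FALSE),
    data.frame(trial = 2, open_side = "right", latency_s = 4,
               hand = "right", approach_side = "right",
               touched_barrier = FALSE, retrieved = TRUE),
    # trial 3 (open front): far-hand style reach is impossible for front;
    # open-side reach without retrieval, then success
    data.frame(trial = 3, open_side = "front", latency_s = 3, hand = "left",
               approach_side = "front", touched_barrier = FALSE,
               retrieved = FALSE),
    data.frame(trial = 3, open_side = "front", latency_s = 3, hand = "left",
               approach_side = "front", touched_barrier = FALSE,
               retrieved = TRUE),
    # trial 4 (open left): perseveration to trial 3's front side (closed
    # now), an awkward far-hand reach, then success
    data.frame(trial = 4, open_side = "left", latency_s = 5, hand = "right",
               approach_side = "front", touched_barrier = FALSE,
               retrieved = FALSE),
    data.frame(trial = 4, open_side = "left", latency_s = 5, hand = "right",
               approach_side = "left", touched_barrier = FALSE,
               retrieved = TRUE))
  o <- derive_ortbd(ortbd_trials(df))
  expect_equal(o$barrier_reach, 1L)
  expect_equal(o$execution_pct, 25)
  expect_equal(o$correct_pct, 100)
  expect_equal(o$perseverative_response, 1L)
  expect_equal(o$awkward_reach, 2L)          # both trial-4 right-hand reaches
  expect_equal(o$reaching_disability, 1L)    # trial 3 first reach
  expect_equal(o$reach_number, 7 / 4)
  expect_equal(o$movement_initiation_time, mean(c(2, 4, 3, 5)))
  expect_equal(sum(o$hand_bias), 7L, ignore_attr = TRUE)
})

test_that("sessions with no attempts are marked degenerate", {
  df <- data.frame(trial = 1:3, open_side = "left", latency_s = NA_real_,
                   hand = NA_character_, approach_side = NA_character_,
                   touched_barrier = NA, retrieved = NA)
  o <- derive_ortbd(ortbd_trials(df))
  expect_equal(o$correct_pct, 0)
  expect_true(is.na(o$movement_initiation_time))
  expect_true(is.na(o$reach_number))
})

test_that("ORTBD invariants hold on simulated sessions", {
  for (seed in 1:5) {
    tr <- simulate_ortbd(ortbd_sim_config(p_success = 0.5), seed = seed)
    o <- derive_ortbd(tr)
    expect_lte(o$execution_pct, o$correct_pct)
    expect_lte(o$correct_pct, 100)
    expect_gte(o$reach_number, 1)
    expect_equal(sum(o$hand_bias), sum(!is.na(tr$hand)), ignore_attr = TRUE)
    reaches <- tr[!is.na(tr$hand), ]
    open_reaches <- sum(reaches$approach_side == reaches$open_side)
    retrieved_open <- sum(reaches$retrieved)
    expect_equal(o$reaching_disability + retrieved_open, open_reaches)
  }
})

test_that("retrieval-ordering violations are rejected", {
  df <- data.frame(trial = c(1, 1), open_side = "left", latency_s = 1,
                   hand = "left", approach_side = "left",
                   touched_barrier = FALSE, retrieved = c(TRUE, FALSE))
  expect_error(ortbd_trials(df), "last reach")
})

test_that("tremor frequency estimates match printed and degenerate cases", {
  one <- tremor_frequency(data.frame(oscillation_count = 43,
                                     duration_s = 10))
  expect_equal(one$mean_hz, 4.3)

  two <- tremor_frequency(data.frame(oscillation_count = c(10, 10),
                                     duration_s = 5))
  expect_equal(two$mean_hz, 2)
  expect_equal(two$sd_hz, 0)

  expect_error(tremor_frequency(data.frame(oscillation_count = 1,
                                           duration_s = 0)), "> 0")
  expect_error(tremor_frequency(data.frame(oscillation_count = -1,
                                           duration_s = 1)), ">= 0")
})
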