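test_that("simple dialect parses records and infers the epoch length", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,count",
               "2018-06-01T09:00:00,5",
               "2018-06-01T09:01:00,0",
               "2018-06-01T09:02:00,12"), path)
  s <- read_epoch_series(path)
  expect_s3_class(s, "epoch_series")
  expect_length(s, 3L)
  expect_equal(s$epoch_seconds, 60L)
  expect_equal(s$counts, c(5, 0, 12))
  expect_equal(format(s$start, "%H:%M"), "09:00")
})

test_that("malformed epoch files are rejected with the offending line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,count"), path)
  expect_error(read_epoch_series(path), "no records")

  writeLines(c("timestamp,count",
               "2018-06-01T09:00:00,5",
               "2018-06-01T09:00:00,3"), path)
  expect_error(read_epoch_series(path), "not strictly increasing|spacing")

  writeLines(c("timestamp,count",
               "2018-06-01T09:00:00,5",
               "2018-06-01T09:01:00,3",
               "2018-06-01T09:03:00,2"), path)
  expect_error(read_epoch_series(path), "non-uniform")

  writeLines(c("timestamp,count",
               "2018-06-01T09:00:00,-4"), path)
  expect_error(read_epoch_series(path), "negative count")

  writeLines(c("timestamp,count",
               "2018-06-01T09:00:00"), path)
  expect_error(read_epoch_series(path), "line 2")
})

test_that("write/read round-trips preserve every field, meta and decimals", {
  s <- epoch_series(c(5, 0, 2.5), "2018-06-03 21:30", 30L,
                    subject_id = "A32829",
                    meta = list(device = "collar-7", cohort = "baseline"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_epoch_series(s, path)
  r <- read_epoch_series(path)
  expect_identical(r$counts, s$counts)
  expect_identical(r$start, s$start)
  expect_identical(r$epoch_seconds, s$epoch_seconds)
  expect_identical(r$subject_id, s$subject_id)
  expect_identical(r$meta$device, "collar-7")
  expect_identical(r$meta$cohort, "baseline")
  expect_match(readLines(path)[1], "^# generator:")
})

test_that("awd dialect reads header epochs codes and count body", {
  path <- withr::local_tempfile(fileext = ".awd")
  writeLines(c("A32827", "01-Jun-2018", "09:00", "4", "3", "V123456", "F",
               as.character(c(10, 0, 3, 7))), path)
  s <- read_epoch_series(path, dialect = "awd")
  expect_equal(s$subject_id, "A32827")
  expect_equal(s$epoch_seconds, 60L)
  expect_equal(s$counts, c(10, 0, 3, 7))
  expect_equal(format(s$start, "%Y-%m-%d %H:%M"), "2018-06-01 09:00")

  writeLines(c("A1", "01-Jun-2018", "09:00", "4", "", "", ""), path)
  expect_error(read_epoch_series(path, dialect = "awd"), "no records")
})

test_that("segment_days cuts 24-h days and reports trimmed remainders", {
  s3 <- make_series(72)
  segs <- segment_days(s3)
  expect_length(segs, 3L)
  expect_true(all(vapply(segs, length, 1L) == 1440L))
  expect_null(attr(segs, "leading"))
  expect_null(attr(segs, "trailing"))

  s1 <- make_series(24)
  expect_length(segment_days(s1), 1L)

  # 30 h starting 07:00: 2 h leading, one day, 4 h trailing
  s30 <- make_series(30, start = "2018-06-01 07:00")
  segs <- segment_days(s30, "09:00")
  expect_length(segs, 1L)
  expect_length(attr(segs, "leading"), 120L)
  expect_length(attr(segs, "trailing"), 240L)
  total <- sum(attr(segs, "leading")$counts) + sum(segs[[1]]$counts) +
    sum(attr(segs, "trailing")$counts)
  expect_equal(total, sum(s30$counts))

  expect_error(segment_days(make_series(23)), "insufficient span")
})

test_that("clip_window honours clock spans including midnight crossings", {
  day <- make_series(24)
  night <- clip_window(day, "19:00", "06:30")
  expect_length(night, 690L)

  expect_identical(clip_window(day, "09:00", "09:00")$counts, day$counts)

  late <- clip_window(day, "23:00", "01:00")
  expect_length(late, 120L)
  expect_equal(format(clock_time(marmact:::epoch_clock_min(late)[1])),
               "23:00")

  expect_error(clip_window(make_series(10), "19:00", "06:30"),
               "not contained")
})

test_that("bin_counts conserves totals and applies the partial-bin policy", {
  s <- make_series(1)
  b <- bin_counts(s, 3600L)
  expect_length(b, 1L)
  expect_equal(b$counts, 60)

  alt <- epoch_series(rep(c(0, 10), 30), "2018-06-01 09:00")
  b10 <- bin_counts(alt, 600L)
  expect_equal(b10$counts, rep(50, 6))

  expect_identical(bin_counts(s, 60L)$counts, s$counts)

  odd <- epoch_series(rep(1, 65), "2018-06-01 09:00")
  expect_error(bin_counts(odd, 3600L), "not divisible")
  expect_message(dropped <- bin_counts(odd, 3600L, partial = "drop"),
                 "dropping")
  expect_equal(dropped$counts, 60)
})

test_that("counts and clock inputs are validated", {
  expect_error(epoch_series(numeric(0), "2018-06-01 09:00"), "length")
  expect_error(epoch_series(c(1, -2), "2018-06-01 09:00"), ">= 0")
  expect_error(epoch_series(c(1, NA), "2018-06-01 09:00"), "finite")
  expect_error(clock_time("24:00"), "out of range")
  expect_error(clock_time("9h30"), "cannot parse")
  expect_equal(unclass(clock_time("19:00")), 1140L)
})
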