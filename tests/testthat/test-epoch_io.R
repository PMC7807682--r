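# Epoch, diary and covariate IO: round trips, conventions, contract errors.

test_that("epoch CSV round-trips losslessly, including missing markers", {
  s <- make_series(c(0L, 100L, 2303L, NA, 5000L), start = "2013-05-01 10:00")
  path <- withr::local_tempfile(fileext = ".csv")
  write_epochs(s, path)
  expect_identical(read_epochs(path), s)

  empty <- epoch_series("p1", ts0(), integer())
  write_epochs(empty, path)
  back <- read_epochs(path)
  expect_length(back$counts, 0L)
})

test_that("epoch rows may arrive shuffled but not duplicated, gapped or negative", {
  path <- withr::local_tempfile(fileext = ".csv")
  s <- make_series(c(0L, 100L, 2303L), start = "2013-05-01 10:00")
  write_epochs(s, path)
  raw <- read.csv(path, colClasses = "character")
  write.csv(raw[c(3, 1, 2), ], path, row.names = FALSE, quote = FALSE)
  expect_identical(read_epochs(path), s)

  write.csv(raw[c(1, 2, 2, 3), ], path, row.names = FALSE, quote = FALSE)
  expect_error(read_epochs(path), "duplicate timestamp",
               class = "actibed_format_error")

  write.csv(raw[c(1, 3), ], path, row.names = FALSE, quote = FALSE)
  expect_error(read_epochs(path), "2013-05-01T10:01",
               class = "actibed_format_error")

  raw2 <- raw
  raw2$vm_cpm[2] <- "-5"
  write.csv(raw2, path, row.names = FALSE, quote = FALSE)
  expect_error(read_epochs(path), "negative count",
               class = "actibed_format_error")
})

test_that("series constructor enforces alignment and integer counts", {
  expect_error(epoch_series("p", ts0() + 30, 0L), "whole minute",
               class = "actibed_format_error")
  expect_error(epoch_series("p", ts0(), c(1L, -2L)), "non-negative",
               class = "actibed_format_error")
  expect_error(epoch_series("", ts0(), 1L), class = "actibed_format_error")
})

test_that("diary CSV round-trips; post-midnight bedtimes attach to the prior night", {
  path <- withr::local_tempfile(fileext = ".csv")
  naps <- data.frame(start = ts0("2013-05-01 13:00"),
                     end = ts0("2013-05-01 13:40"))
  d1 <- diary_day(as.Date("2013-05-01"), ts0("2013-05-01 22:30"),
                  ts0("2013-05-02 06:30"), naps)
  d2 <- diary_day(as.Date("2013-05-02"), ts0("2013-05-03 00:30"),
                  ts0("2013-05-03 09:00"))
  days <- structure(list(d1, d2), participant_id = "p9")
  write_diary(days, path)
  back <- read_diary(path)
  expect_identical(attr(back, "participant_id"), "p9")
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$date, as.Date("2013-05-01"))
  expect_equal(back[[1]]$naps$start, naps$start)
  # the 00:30 bedtime row is dated 2013-05-03 on disk but belongs to 05-02
  raw <- read.csv(path, colClasses = "character")
  expect_equal(raw$date[2], "2013-05-03")
  expect_equal(back[[2]]$date, as.Date("2013-05-02"))
  expect_equal(back[[2]]$bed_time, ts0("2013-05-03 00:30"))
  expect_equal(nightly_tib(back[[2]]), 510)
})

test_that("generated diaries survive a write/read round trip", {
  coh <- generate_cohort(cohort_config(n_participants = 3, seed = 21))
  path <- withr::local_tempfile(fileext = ".csv")
  for (p in coh$participants) {
    write_diary(p$diary, path)
    back <- read_diary(path)
    expect_equal(length(back), length(p$diary))
    for (k in seq_along(back)) {
      expect_equal(back[[k]]$date, p$diary[[k]]$date)
      expect_equal(back[[k]]$bed_time, p$diary[[k]]$bed_time)
      expect_equal(back[[k]]$rise_time, p$diary[[k]]$rise_time)
      expect_equal(nrow(back[[k]]$naps), nrow(p$diary[[k]]$naps))
    }
  }
})

test_that("diary contract errors: rise at/before bed, overlapping naps", {
  expect_error(diary_day(as.Date("2013-05-01"), ts0("2013-05-01 22:00"),
                         ts0("2013-05-01 21:00")),
               "after bed_time", class = "actibed_format_error")
  naps <- data.frame(start = c(ts0("2013-05-01 13:00"),
                               ts0("2013-05-01 13:30")),
                     end = c(ts0("2013-05-01 14:00"),
                             ts0("2013-05-01 15:00")))
  expect_error(diary_day(as.Date("2013-05-01"), ts0("2013-05-01 22:00"),
                         ts0("2013-05-02 07:00"), naps),
               "overlapping naps", class = "actibed_format_error")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,date,bed_time,rise_time",
               "p1,2013-05-01,22:00,22:00"), path)
  expect_error(read_diary(path), class = "actibed_format_error")
})

test_that("covariates round-trip and are validated", {
  path <- withr::local_tempfile(fileext = ".csv")
  cov <- cohort_covariates(generate_cohort(cohort_config(n_participants = 4,
                                                         seed = 5)))
  write_covariates(cov, path)
  expect_equal(read_covariates(path), cov)
  writeLines(c("participant_id,age,sex,sppb_total", "p1,80,female,13"), path)
  expect_error(read_covariates(path), "sppb", class = "actibed_format_error")
})

test_that("binary device exports are refused with CSV instructions", {
  expect_error(read_device_export("x.gt3x"), "vm_cpm",
               class = "actibed_format_error")
})
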