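# Non-wear detection: the 30-min zero-run rule with a single low-spike
# allowance, oracle equivalence, and mask construction.

nw_iv <- function(counts, ...) {
  detect_nonwear(make_series(counts), nonwear_params(...))
}

pad <- function(core) c(500L, core, 500L)

test_that("zero runs qualify at 30 minutes and the spike allowance is one below 100", {
  # exactly 30 zeros between active epochs
  iv <- nw_iv(pad(rep(0L, 30)))
  expect_equal(unname(iv), matrix(c(2L, 31L), 1))
  # 29 zeros: below the minimum duration
  expect_equal(nrow(nw_iv(pad(rep(0L, 29)))), 0L)
  # one spike below 100 inside 31 eligible epochs counts toward the run
  iv <- nw_iv(pad(c(rep(0L, 15), 50L, rep(0L, 15))))
  expect_equal(unname(iv), matrix(c(2L, 32L), 1))
  # a spike at/above the ceiling breaks the run ("below 100" is strict)
  expect_equal(nrow(nw_iv(pad(c(rep(0L, 15), 150L, rep(0L, 15))))), 0L)
  expect_equal(nrow(nw_iv(pad(c(rep(0L, 15), 100L, rep(0L, 15))))), 0L)
  # two spikes: no 30-epoch window with at most one spike
  expect_equal(nrow(nw_iv(pad(c(rep(0L, 10), 50L, rep(0L, 10), 50L,
                                rep(0L, 10))))), 0L)
  # runs truncated by the recording edge still qualify
  expect_equal(unname(nw_iv(c(rep(0L, 30), 500L))),
               matrix(c(1L, 30L), 1))
  expect_equal(unname(nw_iv(rep(0L, 30))), matrix(c(1L, 30L), 1))
  # missing epochs break a run
  expect_equal(nrow(nw_iv(pad(c(rep(0L, 15), NA, rep(0L, 15))))), 0L)
})

test_that("overlapping qualifying windows resolve to earliest-start maximal runs", {
  # 29 zeros, spike, 29 zeros, spike, 29 zeros: the first run absorbs one
  # spike and stops before the second; the remainder still qualifies
  iv <- nw_iv(c(rep(0L, 29), 50L, rep(0L, 29), 50L, rep(0L, 29)))
  expect_equal(unname(iv), cbind(c(1L, 60L), c(59L, 89L)))
  # a failed short prefix must not swallow a later qualifying run
  iv <- nw_iv(c(rep(0L, 5), 50L, rep(0L, 5), 50L, rep(0L, 40), 500L))
  expect_equal(unname(iv), matrix(c(7L, 52L), 1))
})

test_that("detector matches the brute-force oracle on random series", {
  set.seed(42)
  for (rep_i in 1:200) {
    n <- sample(50:1200, 1)
    x <- random_counts(n)
    expect_identical(unname(detect_nonwear(make_series(x))),
                     unname(oracle_nonwear(x)))
  }
})

test_that("detected epochs grow when the rule is relaxed", {
  covered <- function(iv, n) {
    out <- rep(FALSE, n)
    for (k in seq_len(nrow(iv))) out[iv[k, 1]:iv[k, 2]] <- TRUE
    out
  }
  # a detected interval still qualifies as a non-wear window under the
  # relaxed ceiling (all epochs eligible, spikes within allowance), even
  # though newly eligible spikes can re-segment the reported maximal runs
  qualifies <- function(x, s, e, ceiling) {
    seg <- x[s:e]
    all(!is.na(seg) & seg < ceiling) && sum(seg > 0) <= 1L &&
      (e - s + 1L) >= 30L
  }
  set.seed(7)
  for (rep_i in 1:50) {
    x <- random_counts(600)
    iv <- nw_iv(x)
    base <- covered(iv, 600)
    shorter <- covered(nw_iv(x, min_duration = 15L), 600)
    expect_true(all(!base | shorter))   # lower minimum never removes epochs
    for (k in seq_len(nrow(iv))) {
      expect_true(qualifies(x, iv[k, 1], iv[k, 2], 200L))
    }
  }
})

test_that("masks label TIB over NONWEAR and conserve the series length", {
  # all-zero night inside diary TIB stays TIB, not NONWEAR
  s <- flat_day_series(days = 2, cpm = 1000L, bed_clock = "22:30",
                       rise_clock = "06:30")
  diary <- fixture_diary(2, "22:30", "06:30")
  mask <- apply_masks(s, detect_nonwear(s), diary)
  night1 <- (22 * 60 + 31):(24 * 60)        # epochs of 05-01 22:30-24:00
  expect_true(all(mask[night1] == "TIB"))
  expect_equal(length(mask), length(s$counts))
  expect_equal(sum(mask == "WEAR") + sum(mask == "NONWEAR") +
                 sum(mask == "TIB"), length(s$counts))

  # no diary, no zeros: all wear
  s2 <- make_series(rep(800L, 100))
  expect_true(all(apply_masks(s2, detect_nonwear(s2)) == "WEAR"))

  # a 40-min zero run at 14:00 with no diary overlap becomes NONWEAR
  cnt <- rep(800L, 1440)
  cnt[(14 * 60 + 1):(14 * 60 + 40)] <- 0L
  s3 <- make_series(cnt)
  m3 <- apply_masks(s3, detect_nonwear(s3), fixture_diary(1, "22:30", "06:30"))
  expect_true(all(m3[(14 * 60 + 1):(14 * 60 + 40)] == "NONWEAR"))
  expect_true(all(m3[(13 * 60 + 1):(14 * 60)] == "WEAR"))
})

test_that("a genuinely detached diary interval warns and is ignored", {
  s <- make_series(rep(800L, 1440))
  far <- fixture_diary(1, "22:30", "06:30",
                       start_date = as.Date("2013-07-01"))
  expect_warning(m <- apply_masks(s, detect_nonwear(s), far),
                 "outside the recording")
  expect_true(all(m == "WEAR"))
  # the final measurement night starting just past the end clips silently
  late <- fixture_diary(1, "00:30", "08:00",
                        start_date = as.Date("2013-05-02"))
  expect_silent(apply_masks(s, detect_nonwear(s), late))
})
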