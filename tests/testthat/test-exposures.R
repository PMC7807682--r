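# Intensity classification, windowed daily summaries, person-level pooling
# and tertile assignment.

test_that("cut-points classify band boundaries exactly", {
  expect_equal(as.character(classify_intensity(c(0, 2302, 2303, 4999, 5000))),
               c("SB", "SB", "MID", "MID", "HIGH"))
  expect_error(classify_intensity(-1), class = "actibed_domain_error")
})

# series with `wear` epochs of given counts inside the window, rest zeros
window_series <- function(counts_by_minute) {
  cnt <- rep(0L, 1440)
  cnt[seq_along(counts_by_minute) + 5 * 60] <- as.integer(counts_by_minute)
  make_series(cnt)
}

test_that("daily summaries use wear minutes in the 05:00-24:00 window as denominator", {
  s <- window_series(rep(1000L, 600))
  mask <- apply_masks(s, detect_nonwear(s))
  d <- daily_summary(s, mask)
  expect_equal(nrow(d), 1L)
  expect_equal(d$wear_minutes, 600L)
  expect_equal(d$avg_cpm, 1000)
  expect_equal(d$pct_sb, 100)
  expect_true(d$valid)

  s2 <- window_series(c(rep(1000L, 300), rep(3000L, 300)))
  d2 <- daily_summary(s2, apply_masks(s2, detect_nonwear(s2)))
  expect_equal(d2$avg_cpm, 2000)
  expect_equal(d2$pct_sb, 50)
  expect_equal(d2$pct_mid, 50)
  expect_equal(d2$pct_sb + d2$pct_mid + d2$pct_high, 100)

  # 9 h of wear: below the 10-h validity minimum
  s3 <- window_series(rep(1000L, 540))
  expect_false(daily_summary(s3, apply_masks(s3, detect_nonwear(s3)))$valid)
})

test_that("wear outside the summarisation window never contributes", {
  cnt <- rep(0L, 1440)
  cnt[4 * 60 + 31] <- 9000L                 # 04:30, before the window
  cnt[5 * 60 + (1:600)] <- 1000L
  s <- make_series(cnt)
  d <- daily_summary(s, apply_masks(s, detect_nonwear(s)))
  expect_equal(d$wear_minutes, 600L)
  expect_equal(d$avg_cpm, 1000)             # the 04:30 epoch is excluded
  expect_equal(d$pct_high, 0)
})

test_that("a day with no wear is flagged, not mistaken for a zero day", {
  s <- make_series(rep(0L, 1440))
  d <- daily_summary(s, apply_masks(s, detect_nonwear(s)))
  expect_equal(d$wear_minutes, 0L)
  expect_true(is.na(d$avg_cpm))
  expect_false(d$valid)
})

mk_daily <- function(wear, pct_sb, avg = 1500, valid = wear >= 600) {
  n <- length(wear)
  data.frame(date = as.Date("2013-05-01") + seq_len(n) - 1,
             wear_minutes = wear, avg_cpm = avg,
             pct_sb = pct_sb, pct_mid = 100 - pct_sb, pct_high = 0,
             valid = valid)
}

test_that("participants need 4 valid days; pooling weights days by wear time", {
  excl <- participant_exposure(mk_daily(rep(700, 3), rep(60, 3)))
  expect_s3_class(excl, "participant_excluded")
  expect_match(excl$reason, "3 valid day")

  # pooled percentage weights by wear minutes: 68% here, while the plain
  # mean of daily percentages would be 65%
  pe <- participant_exposure(mk_daily(c(600, 600, 600, 1200),
                                      c(60, 60, 60, 80)))
  expect_equal(pe$pct_sb, (3 * 600 * 60 + 1200 * 80) / 3000)
  expect_true(pe$highly_sedentary)          # pooled 68.0
  pe2 <- participant_exposure(mk_daily(rep(600, 4), rep(64, 4)))
  expect_false(pe2$highly_sedentary)
  pe3 <- participant_exposure(mk_daily(rep(600, 4), rep(65, 4)))
  expect_true(pe3$highly_sedentary)

  # identical days: pooled equals the single-day values, both pooling modes
  same <- mk_daily(rep(800, 5), rep(58, 5))
  a <- participant_exposure(same)
  b <- participant_exposure(same, pooling = "mean_of_days")
  expect_equal(a$pct_sb, 58)
  expect_equal(b$pct_sb, 58)
  expect_equal(a$avg_cpm, b$avg_cpm)

  # invalid days never contribute to the pool
  mixed <- mk_daily(c(rep(700, 4), 300), c(rep(50, 4), 100))
  expect_equal(participant_exposure(mixed)$pct_sb, 50)
})

test_that("masked epochs never contribute to the averages", {
  cnt <- rep(0L, 1440)
  cnt[5 * 60 + (1:600)] <- 1000L
  s <- make_series(cnt)
  mask <- apply_masks(s, detect_nonwear(s))
  base <- daily_summary(s, mask)
  # relabel the NONWEAR epochs' counts arbitrarily: summaries must not move
  s2 <- s
  s2$counts[mask == "NONWEAR"] <- 7777L
  expect_equal(daily_summary(s2, mask)[c("avg_cpm", "pct_sb")],
               base[c("avg_cpm", "pct_sb")])
})

test_that("tertiles cut at 1/3 and 2/3 with ties to the lower tertile", {
  expect_equal(as.character(tertile_assign(1:9)),
               rep(c("low", "middle", "high"), each = 3))
  expect_equal(as.character(tertile_assign(c(5, 1, 9))),
               c("middle", "low", "high"))
  expect_error(tertile_assign(rep(3, 5)), "degenerate",
               class = "actibed_domain_error")
  expect_error(tertile_assign(c(1, 2)), class = "actibed_domain_error")

  set.seed(31)
  for (i in 1:20) {
    x <- sample(round(rnorm(30, 100, 10)))   # duplicates straddle the cuts
    lab <- tertile_assign(x)
    o <- sample(30)
    expect_identical(lab[o], tertile_assign(x[o]))  # permutation stability
    # ties at a cut point all land in the lower tertile
    q <- quantile(x, c(1, 2) / 3, names = FALSE)
    expect_true(all(lab[x == q[1]] == "low"))
    expect_true(all(lab[x == q[2]] %in% c("low", "middle")))
  }
})

test_that("pooled band percentages recover the generator mixture weights", {
  cfg <- cohort_config(n_participants = 3, n_days = 7, seed = 17,
                       activity_trait_sd = 0, nap_mean = 0,
                       nonwear_gap_rate = 0,
                       band_mixture = c(0.6, 0.25, 0.15))
  coh <- generate_cohort(cfg)
  for (p in coh$participants) {
    mask <- apply_masks(p$epochs, detect_nonwear(p$epochs), p$diary)
    pe <- participant_exposure(daily_summary(p$epochs, mask), p$diary)
    expect_equal(pe$pct_sb, 60, tolerance = 2 / 60)   # +-2 points
    expect_equal(pe$pct_mid, 25, tolerance = 2 / 25)
    expect_equal(pe$pct_high, 15, tolerance = 2 / 15)
    expect_equal(pe$pct_sb + pe$pct_mid + pe$pct_high, 100)
  }
})
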