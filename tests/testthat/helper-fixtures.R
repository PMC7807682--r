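# Fixture builders and independent oracles used across the suite.

ts0 <- function(x = "2013-05-01 00:00") as.POSIXct(x, tz = "UTC")

make_series <- function(counts, start = "2013-05-01 00:00", id = "p1") {
  epoch_series(id, ts0(start), counts)
}

# Independent brute-force non-wear oracle: for every start position, scan
# forward epoch by epoch to the furthest end obeying the spike allowance;
# then report earliest-starting qualifying intervals, maximally extended,
# resuming after each reported end.
oracle_nonwear <- function(counts, min_duration = 30L, max_spikes = 1L,
                           spike_ceiling = 100L) {
  n <- length(counts)
  max_end <- integer(n)
  for (i in seq_len(n)) {
    j <- i
    spikes <- 0L
    best <- i - 1L
    while (j <= n && !is.na(counts[j]) && counts[j] < spike_ceiling) {
      if (counts[j] > 0L) spikes <- spikes + 1L
      if (spikes > max_spikes) break
      best <- j
      j <- j + 1L
    }
    max_end[i] <- best
  }
  res_s <- integer()
  res_e <- integer()
  i <- 1L
  while (i <= n) {
    if (max_end[i] - i + 1L >= min_duration) {
      res_s <- c(res_s, i)
      res_e <- c(res_e, max_end[i])
      i <- max_end[i] + 1L
    } else {
      i <- i + 1L
    }
  }
  cbind(start = res_s, end = res_e)
}

# random count series mixing scattered counts with structured zero runs and
# low spikes, the regime where run/spike bookkeeping can go wrong
random_counts <- function(n) {
  x <- sample(c(0L, 0L, 50L, 99L, 100L, 150L, 800L, 3000L), n,
              replace = TRUE,
              prob = c(0.25, 0.15, 0.1, 0.05, 0.05, 0.1, 0.15, 0.15))
  # splice in a few structured candidate runs
  for (k in seq_len(max(1L, n %/% 300L))) {
    len <- sample(20:60, 1L)
    if (len + 2L > n) next
    at <- sample(n - len, 1L)
    blk <- integer(len)
    nsp <- sample(0:2, 1L)
    if (nsp > 0L) blk[sample(len, nsp)] <- sample(c(50L, 99L, 120L), nsp,
                                                  replace = TRUE)
    x[at:(at + len - 1L)] <- blk
  }
  x
}

# a flat daytime series: `days` full days, constant `cpm` while awake,
# zeros in bed between bed_clock and rise_clock
flat_day_series <- function(days = 2L, cpm = 3000L, bed_clock = "22:40",
                            rise_clock = "08:20", id = "fx") {
  n <- days * 1440L
  counts <- rep.int(as.integer(cpm), n)
  bed <- clock_minutes(bed_clock)
  rise <- clock_minutes(rise_clock)
  for (d in seq_len(days)) {
    a <- (d - 1L) * 1440L + bed
    b <- (d - 1L) * 1440L + 1440L + rise
    idx <- (a + 1L):b
    counts[idx[idx <= n]] <- 0L
  }
  make_series(counts, id = id)
}

clock_minutes <- function(x) {
  p <- as.integer(strsplit(x, ":", fixed = TRUE)[[1L]])
  p[1L] * 60L + p[2L]
}

fixture_diary <- function(days, bed_clock, rise_clock, id = "fx",
                          start_date = as.Date("2013-05-01")) {
  bed <- clock_minutes(bed_clock)
  rise <- clock_minutes(rise_clock)
  out <- lapply(seq_len(days), function(d) {
    date_d <- start_date + (d - 1L)
    base <- as.POSIXct(paste(date_d), tz = "UTC")
    b <- base + 60 * bed
    r <- b + 60 * ((rise - bed) %% 1440L)
    diary_day(date_d, b, r)
  })
  structure(out, participant_id = id)
}
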