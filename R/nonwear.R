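# Non-wear detection from sustained zero-count runs and construction of the
# per-epoch WEAR / NONWEAR / TIB mask.

#' Non-wear detection parameters
#'
#' Defaults implement the rule: periods of 30 min or longer of continuous
#' zero counts, allowing one single spike below 100 counts, are non-wear.
#' The spike bound is strict (`< spike_ceiling`): an epoch at exactly the
#' ceiling breaks the run. The spike epoch counts toward the duration, and
#' the spike allowance applies once per detected run, not per 30-min window.
#'
#' @param min_duration Minimum run length in minutes (default 30).
#' @param max_spikes Maximum number of tolerated low spikes per run
#'   (default 1).
#' @param spike_ceiling Exclusive upper bound for a spike count (default 100).
#' @return A list of class `nonwear_params`.
#' @export
nonwear_params <- function(min_duration = 30L, max_spikes = 1L,
                           spike_ceiling = 100L) {
  structure(list(
    min_duration = check_count(min_duration, "min_duration", min = 1L),
    max_spikes = check_count(max_spikes, "max_spikes", min = 0L),
    spike_ceiling = check_count(spike_ceiling, "spike_ceiling", min = 1L)
  ), class = "nonwear_params")
}

#' Detect non-wear intervals in a count series
#'
#' Scans for maximal runs of epochs that are all zero except for at most
#' `max_spikes` epochs with `0 < count < spike_ceiling`; runs of at least
#' `min_duration` epochs are reported. Any count at or above the ceiling
#' (and any missing epoch) terminates a candidate run. Runs truncated by the
#' recording edge still qualify if long enough. When qualifying windows
#' overlap, the earliest-starting run is reported, extended as far right as
#' the spike allowance permits, and scanning resumes after its end, so
#' reported intervals never overlap.
#'
#' @param series An [epoch_series()].
#' @param params A [nonwear_params()] list.
#' @return Integer matrix with columns `start`, `end`: 1-based inclusive
#'   epoch indices of detected non-wear intervals (zero rows if none).
#' @examples
#' s <- epoch_series("p", as.POSIXct("2013-05-01 12:00", tz = "UTC"),
#'                   c(500L, rep(0L, 15L), 50L, rep(0L, 15L), 700L))
#' detect_nonwear(s)  # one 31-epoch interval containing the spike
#' @export
detect_nonwear <- function(series, params = nonwear_params()) {
  stopifnot(inherits(series, "epoch_series"))
  cnt <- series$counts
  n <- length(cnt)
  out_s <- integer(); out_e <- integer()
  eligible <- !is.na(cnt) & (cnt == 0L | cnt < params$spike_ceiling)
  spike <- eligible & !is.na(cnt) & cnt > 0L
  if (n) {
    r <- rle(eligible)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (b in which(r$values)) {
      s0 <- starts[b]; e0 <- ends[b]
      sp <- which(spike[s0:e0]) + s0 - 1L   # spike positions in stretch
      i <- s0
      while (i <= e0) {
        ahead <- sp[sp >= i]
        j <- if (length(ahead) <= params$max_spikes) e0
             else ahead[params$max_spikes + 1L] - 1L
        if (j - i + 1L >= params$min_duration) {
          out_s <- c(out_s, i); out_e <- c(out_e, j)
          i <- j + 1L
        } else if (length(ahead)) {
          # no qualifying run starts before the first spike ahead ends later
          i <- ahead[1L] + 1L
        } else break
      }
    }
  }
  cbind(start = out_s, end = out_e)
}

#' Combine non-wear intervals and diary time in bed into a wear mask
#'
#' Labels every epoch `WEAR`, `NONWEAR` or `TIB`. Epochs whose start time
#' falls inside a diary night (bed to rise, half-open) are `TIB`; epochs in
#' detected non-wear intervals (and not in bed) are `NONWEAR`; missing-count
#' epochs are `NONWEAR` (they cannot be attributed to wear); everything else
#' is `WEAR`. TIB takes precedence over NONWEAR. Diary naps are not masked:
#' they remain wear time and typically count as sedentary behaviour.
#'
#' @param series An [epoch_series()].
#' @param nonwear_intervals Matrix from [detect_nonwear()].
#' @param diary List of [diary_day()] entries, or `NULL` for no diary.
#' @return Factor of class `wear_mask` with levels WEAR/NONWEAR/TIB, one
#'   label per epoch. Diary intervals entirely outside the recording raise a
#'   warning and are ignored; partial overlap at the edges is clipped.
#' @export
apply_masks <- function(series, nonwear_intervals, diary = NULL) {
  stopifnot(inherits(series, "epoch_series"))
  n <- length(series$counts)
  lab <- rep.int(1L, n)                    # 1 WEAR, 2 NONWEAR, 3 TIB
  if (length(nonwear_intervals)) {
    for (k in seq_len(nrow(nonwear_intervals))) {
      lab[nonwear_intervals[k, 1L]:nonwear_intervals[k, 2L]] <- 2L
    }
  }
  lab[is.na(series$counts)] <- 2L
  if (!is.null(diary)) {
    series_end <- series$start + 60 * n
    for (d in diary) {
      idx <- interval_epochs(series, d$bed_time, d$rise_time)
      if (!length(idx)) {
        # the final measurement night may start shortly after the recording
        # stops (post-midnight bedtime); only a genuinely detached diary
        # interval warrants a warning
        detached <- d$rise_time <= series$start ||
          d$bed_time >= series_end + 12 * 3600
        if (detached) {
          warning("diary night of ", format(d$date),
                  " lies outside the recording; interval ignored",
                  call. = FALSE)
        }
        next
      }
      lab[idx] <- 3L
    }
  }
  structure(factor(c("WEAR", "NONWEAR", "TIB")[lab],
                   levels = c("WEAR", "NONWEAR", "TIB")),
            class = c("wear_mask", "factor"),
            participant_id = series$participant_id,
            start = series$start)
}

# epoch indices whose start lies in [from, to); clipped to the series
interval_epochs <- function(series, from, to) {
  n <- length(series$counts)
  a <- as.numeric(difftime(from, series$start, units = "mins"))
  b <- as.numeric(difftime(to, series$start, units = "mins"))
  i1 <- max(1L, as.integer(ceiling(a)) + 1L)
  i2 <- min(n, as.integer(ceiling(b)))
  if (i2 < i1) integer() else i1:i2
}
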