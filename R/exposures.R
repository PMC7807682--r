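# Windowed daily and person-level physical-activity / sedentary exposures,
# validity filtering, tertiles, and the highly-sedentary flag.

#' Intensity bands, summarisation window and validity rules
#'
#' Defaults are the wrist vector-magnitude conventions for older adults:
#' sedentary behaviour 0-2302 cpm, higher-intensity bands 2303-4999 and
#' >= 5000 cpm; activity summed over the 05:00-24:00 window (maximum
#' 19 h/day); a valid day has at least 10 h (600 min) of wear; a participant
#' needs at least 4 valid days; highly sedentary means sedentary behaviour
#' occupying at least 65% of wear time.
#'
#' @param sb_upper Inclusive upper bound of the sedentary band (cpm).
#' @param mid_upper Inclusive upper bound of the middle band (cpm).
#' @param window_start,window_end Summarisation window as `"HH:MM"` clock
#'   times (`"24:00"` allowed for end of day).
#' @param min_wear Minimum wear minutes for a valid day.
#' @param min_valid_days Minimum number of valid days to retain a
#'   participant.
#' @param highly_sedentary_threshold Fraction of wear time in sedentary
#'   behaviour at or above which a participant is highly sedentary.
#' @param fixed_sleep_window Fixed sleep-removal window (`"HH:MM"` pair) for
#'   the sensitivity analysis.
#' @return A list of class `intensity_bands`.
#' @export
intensity_bands <- function(sb_upper = 2302L, mid_upper = 4999L,
                            window_start = "05:00", window_end = "24:00",
                            min_wear = 600L, min_valid_days = 4L,
                            highly_sedentary_threshold = 0.65,
                            fixed_sleep_window = c("23:00", "08:00")) {
  sb_upper <- check_count(sb_upper, "sb_upper", min = 1L)
  mid_upper <- check_count(mid_upper, "mid_upper", min = 1L)
  if (sb_upper >= mid_upper) {
    abort("'sb_upper' must be below 'mid_upper'",
          class = "actibed_config_error")
  }
  ws <- if (identical(window_start, "24:00")) 1440L else clock_parse(window_start)
  we <- if (identical(window_end, "24:00")) 1440L else clock_parse(window_end)
  if (ws >= we) {
    abort("'window_start' must precede 'window_end'",
          class = "actibed_config_error")
  }
  check_number(highly_sedentary_threshold, "highly_sedentary_threshold",
               min = 0, max = 1, strict_min = TRUE)
  if (highly_sedentary_threshold >= 1) {
    abort("'highly_sedentary_threshold' must be below 1",
          class = "actibed_config_error")
  }
  structure(list(
    sb_upper = sb_upper, mid_upper = mid_upper,
    window_start = ws, window_end = we,
    min_wear = check_count(min_wear, "min_wear", min = 1L),
    min_valid_days = check_count(min_valid_days, "min_valid_days", min = 1L),
    highly_sedentary_threshold = highly_sedentary_threshold,
    fixed_sleep_window = vapply(fixed_sleep_window, clock_parse, 1L,
                                USE.NAMES = FALSE)
  ), class = "intensity_bands")
}

#' Classify counts per minute into intensity bands
#'
#' @param cpm Numeric vector of non-negative counts per minute.
#' @param bands An [intensity_bands()] list.
#' @return Factor with levels `SB` (0-2302), `MID` (2303-4999) and `HIGH`
#'   (>= 5000) under the default cut-points.
#' @examples
#' classify_intensity(c(0, 2302, 2303, 4999, 5000))
#' @export
classify_intensity <- function(cpm, bands = intensity_bands()) {
  if (any(!is.na(cpm) & cpm < 0)) {
    abort("counts per minute must be non-negative",
          class = "actibed_domain_error")
  }
  cut(cpm, breaks = c(-Inf, bands$sb_upper, bands$mid_upper, Inf),
      labels = c("SB", "MID", "HIGH"))
}

#' Daily wear-time activity summaries
#'
#' Summarises each calendar day of a masked series: only `WEAR` epochs whose
#' start lies inside the summarisation window contribute. Average cpm is
#' total counts over wear minutes; band percentages use wear minutes as the
#' denominator. A day with fewer wear minutes than `min_wear` is invalid; a
#' day with zero wear minutes has undefined (`NA`) averages and percentages.
#'
#' @param series An [epoch_series()].
#' @param mask A `wear_mask` aligned with `series` (see [apply_masks()]).
#' @param bands An [intensity_bands()] list.
#' @return Data frame with one row per calendar day spanned by the series:
#'   `date`, `wear_minutes`, `avg_cpm`, `pct_sb`, `pct_mid`, `pct_high`,
#'   `valid`.
#' @export
daily_summary <- function(series, mask, bands = intensity_bands()) {
  stopifnot(inherits(series, "epoch_series"))
  if (length(mask) != length(series$counts)) {
    abort("mask and series are not aligned", class = "actibed_domain_error")
  }
  t <- epoch_times(series)
  mod <- minute_of_day(t)
  day <- as.Date(t, tz = "UTC")
  in_window <- mod >= bands$window_start & mod < bands$window_end
  contrib <- in_window & unclass(mask) == 1L & !is.na(series$counts)
  days <- sort(unique(day))
  band <- classify_intensity(ifelse(is.na(series$counts), 0L, series$counts),
                             bands)
  res <- lapply(days, function(d) {
    sel <- contrib & day == d
    wear <- sum(sel)
    if (wear == 0L) {
      return(data.frame(date = d, wear_minutes = 0L, avg_cpm = NA_real_,
                        pct_sb = NA_real_, pct_mid = NA_real_,
                        pct_high = NA_real_, valid = FALSE))
    }
    cts <- series$counts[sel]
    b <- band[sel]
    data.frame(date = d, wear_minutes = wear,
               avg_cpm = sum(cts) / wear,
               pct_sb = 100 * sum(b == "SB") / wear,
               pct_mid = 100 * sum(b == "MID") / wear,
               pct_high = 100 * sum(b == "HIGH") / wear,
               valid = wear >= bands$min_wear)
  })
  out <- do.call(rbind, res)
  row.names(out) <- NULL
  out
}

#' Person-level pooled exposures
#'
#' Pools epochs across valid days: average cpm is total counts over total
#' wear minutes and band percentages are total band minutes over total wear
#' minutes (not means of daily percentages; set `pooling = "mean_of_days"`
#' for that alternative). A participant is retained only with at least
#' `min_valid_days` valid days; otherwise an object of class
#' `participant_excluded` carrying the reason is returned. Highly sedentary
#' means the pooled
#' sedentary percentage reaches `100 * highly_sedentary_threshold`.
#'
#' @param daily Data frame from [daily_summary()].
#' @param diary List of [diary_day()] entries (for nap length), or `NULL`.
#' @param bands An [intensity_bands()] list.
#' @param pooling `"pooled"` (default) or `"mean_of_days"`.
#' @return A one-row data frame with `avg_cpm`, `pct_sb`, `pct_mid`,
#'   `pct_high`, `highly_sedentary`, `avg_nap_minutes`, `n_valid_days` and
#'   `wear_minutes_per_day`, or a `participant_excluded` object if the
#'   participant fails the validity rule.
#' @export
participant_exposure <- function(daily, diary = NULL,
                                 bands = intensity_bands(),
                                 pooling = c("pooled", "mean_of_days")) {
  pooling <- match.arg(pooling)
  if (!nrow(daily)) {
    abort("at least one daily summary required",
          class = "actibed_domain_error")
  }
  ok <- daily$valid
  n_valid <- sum(ok)
  if (n_valid < bands$min_valid_days) {
    return(structure(
      list(reason = sprintf("%d valid day(s) (<%d)", n_valid,
                            bands$min_valid_days)),
      class = "participant_excluded"))
  }
  v <- daily[ok, , drop = FALSE]
  wear <- sum(v$wear_minutes)
  if (pooling == "pooled") {
    avg_cpm <- sum(v$avg_cpm * v$wear_minutes) / wear
    pct_sb <- sum(v$pct_sb * v$wear_minutes) / wear
    pct_mid <- sum(v$pct_mid * v$wear_minutes) / wear
    pct_high <- sum(v$pct_high * v$wear_minutes) / wear
  } else {
    avg_cpm <- mean(v$avg_cpm)
    pct_sb <- mean(v$pct_sb)
    pct_mid <- mean(v$pct_mid)
    pct_high <- mean(v$pct_high)
  }
  avg_nap <- if (is.null(diary) || !length(diary)) 0
             else mean(vapply(diary, nap_minutes, numeric(1)))
  data.frame(
    avg_cpm = avg_cpm, pct_sb = pct_sb, pct_mid = pct_mid,
    pct_high = pct_high,
    highly_sedentary = pct_sb >= 100 * bands$highly_sedentary_threshold,
    avg_nap_minutes = avg_nap,
    n_valid_days = n_valid,
    wear_minutes_per_day = wear / n_valid
  )
}

#' Assign cohort tertiles
#'
#' Cuts a person-level metric at its empirical 1/3 and 2/3 quantiles
#' (inclusive linear-interpolation quantiles, base type 7). Values equal to
#' a cut point go to the lower tertile, so the assignment is deterministic
#' and stable under permutation of the input.
#'
#' @param values Numeric vector over the retained cohort (length >= 3).
#' @return Factor with levels `low`, `middle`, `high` (low first, the
#'   modelling reference).
#' @examples
#' tertile_assign(1:9)
#' @export
tertile_assign <- function(values) {
  if (length(values) < 3L || anyNA(values)) {
    abort("need at least 3 non-missing values",
          class = "actibed_domain_error")
  }
  q <- stats::quantile(values, c(1, 2) / 3, names = FALSE, type = 7)
  if (diff(range(values)) == 0) {
    abort("all values identical: tertiles are degenerate",
          class = "actibed_domain_error")
  }
  lab <- ifelse(values <= q[1L], "low",
                ifelse(values <= q[2L], "middle", "high"))
  factor(lab, levels = c("low", "middle", "high"))
}
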