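# Nightly time in bed and the UTIB / STIB / RTIB categorisation.

#' Time-in-bed categorisation rule
#'
#' Nightly time in bed between `range_low` and `range_high` hours (closed on
#' both ends, default 7-9 h) counts as in range. Participants are labelled by
#' the percentage `p` of measurement nights in range: `UTIB` (usually,
#' `p >= utib_min`), `RTIB` (rarely, `p < rtib_max`) and `STIB` (sometimes)
#' otherwise, so the three intervals tile 0-100% exactly (the printed
#' "20-79%" is integer shorthand implemented as `[20%, 80%)`).
#'
#' @param range_low,range_high Appropriate nightly range in hours.
#' @param utib_min Minimum percent of nights in range for UTIB (default 80).
#' @param rtib_max Exclusive percent bound below which RTIB applies
#'   (default 20).
#' @return A list of class `tib_rule`.
#' @export
tib_rule <- function(range_low = 7, range_high = 9,
                     utib_min = 80, rtib_max = 20) {
  range_low <- check_number(range_low, "range_low", min = 0)
  range_high <- check_number(range_high, "range_high", min = 0)
  if (range_low >= range_high) {
    abort("'range_low' must be below 'range_high'",
          class = "actibed_config_error")
  }
  utib_min <- check_number(utib_min, "utib_min", min = 0, max = 100)
  rtib_max <- check_number(rtib_max, "rtib_max", min = 0, max = 100)
  if (!(rtib_max > 0 && rtib_max < utib_min && utib_min < 100)) {
    abort("need 0 < rtib_max < utib_min < 100",
          class = "actibed_config_error")
  }
  structure(list(range_low = range_low, range_high = range_high,
                 utib_min = utib_min, rtib_max = rtib_max),
            class = "tib_rule")
}

#' Is a night's time in bed within the appropriate range?
#'
#' @param tib_minutes Positive nightly time in bed in minutes (vectorised).
#' @param rule A [tib_rule()].
#' @return Logical: `TRUE` iff `tib_minutes` lies in
#'   `[60 * range_low, 60 * range_high]`, both ends inclusive (420-540 min
#'   by default).
#' @examples
#' tib_in_range(c(419, 420, 501, 540, 541))
#' @export
tib_in_range <- function(tib_minutes, rule = tib_rule()) {
  if (any(!is.na(tib_minutes) & tib_minutes <= 0)) {
    abort("tib_minutes must be positive", class = "actibed_domain_error")
  }
  tib_minutes >= 60 * rule$range_low & tib_minutes <= 60 * rule$range_high
}

#' Categorise a participant as UTIB, STIB or RTIB
#'
#' @param nights_in_range Number of measurement nights with time in bed in
#'   the appropriate range.
#' @param nights_total Total number of measurement nights (>= 1); nights
#'   without a complete diary entry are not counted.
#' @param rule A [tib_rule()].
#' @return Factor level among `UTIB`, `STIB`, `RTIB` (UTIB first, the
#'   modelling reference). With `p = 100 * nights_in_range / nights_total`:
#'   UTIB iff `p >= 80`, RTIB iff `p < 20`, STIB otherwise.
#' @examples
#' tib_categorize(6, 7)  # UTIB
#' tib_categorize(1, 7)  # RTIB
#' @export
tib_categorize <- function(nights_in_range, nights_total,
                           rule = tib_rule()) {
  nights_total <- check_count(nights_total, "nights_total", min = 1L)
  nights_in_range <- check_count(nights_in_range, "nights_in_range",
                                 min = 0L)
  if (nights_in_range > nights_total) {
    abort("nights_in_range exceeds nights_total",
          class = "actibed_domain_error")
  }
  p <- 100 * nights_in_range / nights_total
  lab <- if (p >= rule$utib_min) "UTIB"
         else if (p < rule$rtib_max) "RTIB"
         else "STIB"
  factor(lab, levels = c("UTIB", "STIB", "RTIB"))
}

# internal: full diary -> category + median nightly TIB
tib_from_diary <- function(diary, rule = tib_rule()) {
  tibs <- nightly_tib(diary)
  tibs <- tibs[!is.na(tibs)]
  if (!length(tibs)) {
    abort("no complete diary nights: TIB category undefined",
          class = "actibed_domain_error")
  }
  list(category = tib_categorize(sum(tib_in_range(tibs, rule)),
                                 length(tibs), rule),
       median_tib = stats::median(tibs),
       nights = length(tibs))
}
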