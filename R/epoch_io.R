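# Epoch, diary and covariate file formats plus the timestamp conventions used
# by every other module. Epochs are half-open minutes [t, t + 60 s); an epoch
# belongs to a calendar day by its start time.

#' Per-minute epoch count series
#'
#' Container for one participant's timestamped per-minute vector-magnitude
#' counts. Epochs are contiguous 60-s intervals; missing data are represented
#' by `NA` counts, never by absent rows.
#'
#' @param participant_id Opaque participant identifier (single string).
#' @param start POSIXct start of the first epoch, aligned to a whole minute.
#' @param counts Integer vector of non-negative vector-magnitude counts per
#'   minute; `NA` marks a missing epoch.
#' @return An object of class `epoch_series` with fields `participant_id`,
#'   `start` and `counts`.
#' @examples
#' s <- epoch_series("p1", as.POSIXct("2013-05-01 00:00", tz = "UTC"),
#'                   c(0L, 120L, 2303L))
#' epoch_times(s)
#' @export
epoch_series <- function(participant_id, start, counts) {
  if (!is.character(participant_id) || length(participant_id) != 1L ||
      is.na(participant_id) || !nzchar(participant_id)) {
    abort("participant_id must be a non-empty string",
          class = "actibed_format_error")
  }
  start <- as.POSIXct(start, tz = "UTC")
  if (length(start) != 1L || is.na(start) ||
      as.numeric(start) %% 60 != 0) {
    abort("start must be a single timestamp aligned to a whole minute",
          class = "actibed_format_error")
  }
  counts <- as.vector(counts)
  if (length(counts) &&
      any(!is.na(counts) & (counts < 0 | counts != floor(counts)))) {
    abort("counts must be non-negative integers (NA allowed)",
          class = "actibed_format_error")
  }
  structure(
    list(participant_id = participant_id, start = start,
         counts = as.integer(counts)),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  n <- length(x$counts)
  cat(sprintf("<epoch_series> %s: %d epochs (60 s) from %s, %d missing\n",
              x$participant_id, n, ts_format(x$start), sum(is.na(x$counts))))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$counts)

#' Epoch start timestamps of a series
#' @param series An [epoch_series()].
#' @return POSIXct vector, one start time per epoch.
#' @export
epoch_times <- function(series) {
  series$start + 60 * (seq_along(series$counts) - 1L)
}

#' One diary entry: a night in bed and the day's naps
#'
#' A diary day is anchored on the calendar date of the evening it describes.
#' `bed_time` may fall after midnight (then on `date + 1`); `rise_time` is the
#' first matching clock time after `bed_time`.
#'
#' @param date Calendar `Date` of the diary day (the waking day preceding the
#'   night).
#' @param bed_time,rise_time POSIXct bed and rise timestamps with
#'   `rise_time > bed_time`.
#' @param naps Optional data frame with POSIXct columns `start`, `end`:
#'   non-overlapping nap intervals during the day's waking hours.
#' @return An object of class `diary_day`.
#' @export
diary_day <- function(date, bed_time, rise_time, naps = NULL) {
  date <- as.Date(date)
  bed_time <- as.POSIXct(bed_time, tz = "UTC")
  rise_time <- as.POSIXct(rise_time, tz = "UTC")
  if (is.na(bed_time) || is.na(rise_time)) {
    abort("bed_time and rise_time must both be present",
          class = "actibed_format_error")
  }
  if (rise_time <= bed_time) {
    abort("rise_time (", ts_format(rise_time), ") must be after bed_time (",
          ts_format(bed_time), ")", class = "actibed_format_error")
  }
  if (is.null(naps)) {
    naps <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                       end = as.POSIXct(character(), tz = "UTC"))
  }
  if (nrow(naps)) {
    naps <- naps[order(naps$start), , drop = FALSE]
    row.names(naps) <- NULL
    if (any(naps$end <= naps$start)) {
      abort("nap end must be after nap start", class = "actibed_format_error")
    }
    if (nrow(naps) > 1L &&
        any(naps$start[-1L] < naps$end[-nrow(naps)])) {
      abort("overlapping naps in diary day ", format(date),
            class = "actibed_format_error")
    }
  }
  structure(list(date = date, bed_time = bed_time, rise_time = rise_time,
                 naps = naps),
            class = "diary_day")
}

#' @export
print.diary_day <- function(x, ...) {
  cat(sprintf("<diary_day> %s: bed %s rise %s, %d nap(s)\n",
              format(x$date), ts_format(x$bed_time), ts_format(x$rise_time),
              nrow(x$naps)))
  invisible(x)
}

#' Nightly time in bed of one diary day, in minutes
#' @param day A [diary_day()] (or a list of them, returning a vector).
#' @return Minutes from going to bed until getting out of bed the next day.
#' @examples
#' d <- diary_day(as.Date("2013-05-01"),
#'                as.POSIXct("2013-05-01 22:30", tz = "UTC"),
#'                as.POSIXct("2013-05-02 06:30", tz = "UTC"))
#' nightly_tib(d) # 480
#' @export
nightly_tib <- function(day) {
  if (inherits(day, "diary_day")) {
    return(as.numeric(difftime(day$rise_time, day$bed_time, units = "mins")))
  }
  vapply(day, nightly_tib, numeric(1))
}

nap_minutes <- function(day) {
  if (!nrow(day$naps)) return(0)
  sum(as.numeric(difftime(day$naps$end, day$naps$start, units = "mins")))
}

## ---------------------------------------------------------------------------
## Epoch CSV: participant_id,timestamp,vm_cpm  (ISO-8601 minute; NA = missing)

#' Read a per-minute epoch count series
#'
#' Reads the epoch CSV dialect `participant_id,timestamp,vm_cpm` (UTF-8,
#' comma-delimited, header mandatory; timestamps at minute precision). Rows
#' may be out of order; duplicate timestamps, negative counts and gaps in the
#' minute grid are format errors. A missing epoch must be written as `NA`,
#' not omitted.
#'
#' @param path Path to the CSV file.
#' @param participant_id Optional id to select when the file holds several
#'   participants; with one participant it may be omitted.
#' @return An [epoch_series()].
#' @export
read_epochs <- function(path, participant_id = NULL) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  need <- c("participant_id", "timestamp", "vm_cpm")
  if (!all(need %in% names(raw))) {
    abort("epoch CSV must have header participant_id,timestamp,vm_cpm",
          class = "actibed_format_error")
  }
  if (!nrow(raw)) {
    return(epoch_series(participant_id %||% "unknown",
                        as.POSIXct("1970-01-01 00:00", tz = "UTC"),
                        integer()))
  }
  ids <- unique(raw$participant_id)
  if (is.null(participant_id)) {
    if (length(ids) > 1L) {
      abort("file holds ", length(ids),
            " participants; pass participant_id (one of: ",
            paste(utils::head(ids, 5L), collapse = ", "), " ...)",
            class = "actibed_format_error")
    }
    participant_id <- ids
  }
  raw <- raw[raw$participant_id == participant_id, , drop = FALSE]
  if (!nrow(raw)) {
    return(epoch_series(participant_id,
                        as.POSIXct("1970-01-01 00:00", tz = "UTC"),
                        integer()))
  }
  t <- ts_parse(raw$timestamp)
  o <- order(t)
  t <- t[o]
  raw_cnt <- raw$vm_cpm[o]
  cnt <- suppressWarnings(as.integer(raw_cnt))
  bad <- is.na(cnt) & !is.na(raw_cnt) & !(raw_cnt %in% c("NA", "", "na"))
  if (any(bad)) {
    abort("non-integer count '", raw_cnt[which(bad)[1L]], "' at ",
          ts_format(t[which(bad)[1L]]), class = "actibed_format_error")
  }
  if (any(!is.na(cnt) & cnt < 0)) {
    i <- which(!is.na(cnt) & cnt < 0)[1L]
    abort("negative count at ", ts_format(t[i]),
          class = "actibed_format_error")
  }
  d <- diff(as.numeric(t))
  if (any(d == 0)) {
    abort("duplicate timestamp ", ts_format(t[which(d == 0)[1L]]),
          class = "actibed_format_error")
  }
  if (any(d != 60)) {
    i <- which(d != 60)[1L]
    abort("gap in epoch grid: first missing minute at ",
          ts_format(t[i] + 60), " (use NA counts for missing epochs)",
          class = "actibed_format_error")
  }
  epoch_series(participant_id, t[1L], cnt)
}

#' Write a per-minute epoch count series
#' @param series An [epoch_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly. `read_epochs(write_epochs(x))` is the identity.
#' @export
write_epochs <- function(series, path) {
  stopifnot(inherits(series, "epoch_series"))
  df <- if (!length(series$counts)) {
    data.frame(participant_id = character(), timestamp = character(),
               vm_cpm = integer())
  } else {
    data.frame(participant_id = series$participant_id,
               timestamp = ts_format(epoch_times(series)),
               vm_cpm = series$counts)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

# internal: split a multi-participant epoch CSV into series
read_epochs_all <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  ids <- unique(raw$participant_id)
  stats::setNames(lapply(ids, function(id) read_epochs(path, id)), ids)
}

## ---------------------------------------------------------------------------
## Diary CSV: participant_id,date,bed_time,rise_time[,nap1_start,nap1_end,...]
## Clock times HH:MM. A bed_time clock in [00:00, 05:00) belongs to the night
## of the PREVIOUS calendar date; the row's naps follow the diary day.

#' Read a wear-time diary
#'
#' Reads the diary CSV dialect (`participant_id,date,bed_time,rise_time`
#' plus optional `napN_start,napN_end` column pairs, clock times `HH:MM`).
#' Bed times between 24:00 and 05:00 are attached to the preceding night:
#' a row dated `d` with bed time 00:30 yields a diary day dated `d - 1`
#' whose night starts at 00:30 on `d`. `rise_time` is resolved to the first
#' matching clock time after `bed_time`.
#'
#' @inheritParams read_epochs
#' @return A list of [diary_day()] objects ordered by date, with the
#'   participant id attached as attribute `participant_id`.
#' @export
read_diary <- function(path, participant_id = NULL) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  need <- c("participant_id", "date", "bed_time", "rise_time")
  if (!all(need %in% names(raw))) {
    abort("diary CSV must have header participant_id,date,bed_time,rise_time",
          class = "actibed_format_error")
  }
  ids <- unique(raw$participant_id)
  if (is.null(participant_id)) {
    if (length(ids) > 1L) {
      abort("file holds ", length(ids),
            " participants; pass participant_id",
            class = "actibed_format_error")
    }
    participant_id <- ids
  }
  raw <- raw[raw$participant_id == participant_id, , drop = FALSE]
  nap_starts <- grep("^nap[0-9]+_start$", names(raw), value = TRUE)
  days <- lapply(seq_len(nrow(raw)), function(i) {
    row_date <- as.Date(raw$date[i])
    if (is.na(row_date)) {
      abort("unparseable date '", raw$date[i], "'",
            class = "actibed_format_error")
    }
    bed_min <- clock_parse(raw$bed_time[i])
    rise_min <- clock_parse(raw$rise_time[i])
    after_midnight <- bed_min < 300L        # 00:00-04:59 -> prior night
    entry_date <- row_date - after_midnight
    bed <- as.POSIXct(paste(row_date), tz = "UTC") + 60 * bed_min
    span <- (rise_min - bed_min) %% 1440L
    if (span == 0L) {
      abort("rise_time must differ from bed_time (row ", i, ")",
            class = "actibed_format_error")
    }
    rise <- bed + 60 * span
    naps <- NULL
    if (length(nap_starts)) {
      st <- en <- c()
      for (cs in nap_starts) {
        ce <- sub("_start$", "_end", cs)
        if (!ce %in% names(raw)) next
        v1 <- raw[[cs]][i]; v2 <- raw[[ce]][i]
        if (is.na(v1) || !nzchar(v1)) next
        if (is.na(v2) || !nzchar(v2)) {
          abort("nap with start but no end (row ", i, ")",
                class = "actibed_format_error")
        }
        st <- c(st, clock_parse(v1)); en <- c(en, clock_parse(v2))
      }
      if (length(st)) {
        base <- as.POSIXct(paste(entry_date), tz = "UTC")
        naps <- data.frame(start = base + 60 * st, end = base + 60 * en)
      }
    }
    diary_day(entry_date, bed, rise, naps)
  })
  days <- days[order(vapply(days, function(d) as.numeric(d$date), 1))]
  structure(days, participant_id = participant_id)
}

#' Write a wear-time diary
#' @param days List of [diary_day()] objects (as from [read_diary()]).
#' @param path Output CSV path.
#' @param participant_id Participant id column value; defaults to the
#'   `participant_id` attribute of `days`.
#' @return `path`, invisibly. Round-trips losslessly through [read_diary()].
#' @export
write_diary <- function(days, path, participant_id = NULL) {
  participant_id <- participant_id %||% attr(days, "participant_id") %||%
    abort("participant_id required", class = "actibed_format_error")
  max_naps <- max(c(0L, vapply(days, function(d) nrow(d$naps), 1L)))
  rows <- lapply(days, function(d) {
    r <- list(participant_id = participant_id,
              # row date = calendar date of bed_time, so that post-midnight
              # bed times re-attach to the prior night on read
              date = format(as.Date(d$bed_time, tz = "UTC")),
              bed_time = clock_format(minute_of_day(d$bed_time)),
              rise_time = clock_format(minute_of_day(d$rise_time)))
    if (max_naps > 0L) {
      for (j in seq_len(max_naps)) {
        r[[paste0("nap", j, "_start")]] <-
          if (j <= nrow(d$naps)) clock_format(minute_of_day(d$naps$start[j]))
          else ""
        r[[paste0("nap", j, "_end")]] <-
          if (j <= nrow(d$naps)) clock_format(minute_of_day(d$naps$end[j]))
          else ""
      }
    }
    as.data.frame(r, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    cols <- c("participant_id", "date", "bed_time", "rise_time")
    df <- as.data.frame(stats::setNames(
      rep(list(character()), length(cols)), cols))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

read_diary_all <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  ids <- unique(raw$participant_id)
  stats::setNames(lapply(ids, function(id) read_diary(path, id)), ids)
}

## ---------------------------------------------------------------------------
## Covariates CSV: participant_id,age,sex,sppb_total

#' Read / write the covariate table
#'
#' Covariate CSV dialect: `participant_id,age,sex,sppb_total` with
#' `sex` in `{female, male}` and the lower-extremity function score
#' `sppb_total` an integer in 0-12.
#'
#' @param path CSV path.
#' @return `read_covariates()`: a data frame with those four columns, `sex`
#'   as a factor with male as the first (reference) level.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "age", "sex", "sppb_total")
  if (!all(need %in% names(df))) {
    abort("covariates CSV must have header participant_id,age,sex,sppb_total",
          class = "actibed_format_error")
  }
  if (any(!df$sex %in% c("female", "male"))) {
    abort("sex must be 'female' or 'male'", class = "actibed_format_error")
  }
  if (any(df$sppb_total < 0 | df$sppb_total > 12)) {
    abort("sppb_total must lie in [0, 12]", class = "actibed_format_error")
  }
  df$sex <- factor(df$sex, levels = c("male", "female"))
  df[need]
}

#' @rdname read_covariates
#' @param covariates Data frame as returned by `read_covariates()`.
#' @export
write_covariates <- function(covariates, path) {
  df <- covariates[c("participant_id", "age", "sex", "sppb_total")]
  df$sex <- as.character(df$sex)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Expected epoch CSV for device exports
#'
#' Binary ActiGraph containers (.gt3x, .agd) are produced upstream by the
#' vendor toolchain and are out of scope here: export 60-s epoch
#' vector-magnitude counts to CSV first. This stub documents the expected
#' dialect and always fails with that instruction.
#'
#' @param path Path to a device export (unused).
#' @export
read_device_export <- function(path) {
  abort("binary device exports are not supported; export 60-s epoch ",
        "vector-magnitude counts to CSV with header ",
        "participant_id,timestamp,vm_cpm (ISO-8601 minute timestamps) ",
        "and use read_epochs()", class = "actibed_format_error")
}
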