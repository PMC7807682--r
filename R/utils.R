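# Internal helpers shared across modules. All timestamps in the package are
# naive local clock times stored as POSIXct in UTC (no DST transitions).

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(..., class = "actibed_error") {
  stop(errorCondition(paste0(...), class = c(class, "actibed_error")))
}

#' @noRd
ts_parse <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M", tz = "UTC")
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    abort("unparseable timestamp: '", x[which(bad)[1L]],
          "' (expected ISO-8601 minute, e.g. 2013-05-01T10:00)",
          class = "actibed_format_error")
  }
  out
}

ts_format <- function(x) format(x, "%Y-%m-%dT%H:%M", tz = "UTC")

# "HH:MM" -> minutes past midnight
clock_parse <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    abort("unparseable clock time: '", x[which(bad)[1L]], "' (expected HH:MM)",
          class = "actibed_format_error")
  }
  vapply(m, function(p) as.integer(p[2L]) * 60L + as.integer(p[3L]), 1L)
}

clock_format <- function(minutes) {
  minutes <- as.integer(round(minutes)) %% 1440L
  sprintf("%02d:%02d", minutes %/% 60L, minutes %% 60L)
}

# minute-of-day of a POSIXct vector
minute_of_day <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  lt$hour * 60L + lt$min
}

stopifnot_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort("'", name, "' must be TRUE or FALSE", class = "actibed_config_error")
  }
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    abort("'", name, "' must be an integer >= ", min,
          class = "actibed_config_error")
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x > max ||
      (if (strict_min) x <= min else x < min)) {
    abort("'", name, "' must be a number in [",
          if (strict_min) paste0("(", min) else min, ", ", max, "]",
          class = "actibed_config_error")
  }
  as.numeric(x)
}

# Evaluate expr with a private RNG stream; the caller's .Random.seed is
# restored afterwards so seeded generation never perturbs user code.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(expr)
}

# statistical mode of a factor/character vector; ties broken by level order
stat_mode <- function(x) {
  tab <- table(x)
  names(tab)[which.max(tab)]
}

fmt_min <- function(m) {
  sprintf("%d h %02d min", as.integer(m) %/% 60L, as.integer(round(m)) %% 60L)
}
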