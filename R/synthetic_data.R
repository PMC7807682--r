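# Seeded synthetic cohorts: per-minute count series, bedtime diaries and
# covariates with the statistical structure the downstream analysis assumes
# (7-day wrist recordings in 75+ community-dwelling adults). Distributional
# forms are conventions chosen to reproduce published cohort descriptives,
# not claims about any real cohort.

#' Synthetic cohort configuration
#'
#' Defaults emulate a cohort of 75+ community-dwelling adults wearing a
#' wrist accelerometer for 7 days: nightly time in bed centred at
#' 8 h 21 min (501 min) with between-person spread 52 min and night-to-night
#' jitter 45 min (together matching an overall IQR near 70 min), bedtimes
#' around 22:45 (a minority fall after midnight), about 40 min/day of naps,
#' daytime counts from a three-regime mixture occupying the sedentary /
#' 2303-4999 / >=5000 cpm bands with weights 0.64 / 0.23 / 0.13, and about
#' one shower non-wear gap every second day. A latent activity trait shifts
#' the band mixture per participant, correlates negatively with nightly time
#' in bed and positively with the physical-function score, so sedentariness,
#' long nights and low function co-occur.
#'
#' @param n_participants Number of participants.
#' @param n_days Number of recorded days (default 7).
#' @param epoch_length Epoch length in seconds; fixed at 60.
#' @param tib_mean Mean nightly time in bed, minutes.
#' @param tib_sd Between-person SD of mean nightly time in bed, minutes.
#' @param tib_irregularity Night-to-night SD within person, minutes.
#' @param bedtime_mean Mean bedtime as `"HH:MM"`.
#' @param nap_mean Mean total nap length per day, minutes (0 for no naps).
#' @param activity_trait_sd SD of the latent activity trait on the mixture
#'   logit scale (0 removes between-person activity differences).
#' @param band_mixture Three non-negative weights over the low / mid / high
#'   count regimes, summing to 1.
#' @param nonwear_gap_rate Expected shower/non-wear gaps per day.
#' @param inbed_counts_zero If `TRUE` (default) counts during time in bed
#'   are exactly zero; if `FALSE`, low-level restlessness noise is added.
#' @param seed Integer seed; identical config + seed reproduces the cohort
#'   bit for bit.
#' @param start_date First calendar date of the recording.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 341L, n_days = 7L,
                          epoch_length = 60L,
                          tib_mean = 501, tib_sd = 52,
                          tib_irregularity = 45,
                          bedtime_mean = "22:45",
                          nap_mean = 40,
                          activity_trait_sd = 0.3,
                          band_mixture = c(0.64, 0.23, 0.13),
                          nonwear_gap_rate = 0.5,
                          inbed_counts_zero = TRUE,
                          seed = 1L,
                          start_date = as.Date("2013-05-01")) {
  if (!identical(as.integer(epoch_length), 60L)) {
    abort("'epoch_length' is fixed at 60 s", class = "actibed_config_error")
  }
  if (!is.numeric(band_mixture) || length(band_mixture) != 3L ||
      any(band_mixture < 0) || abs(sum(band_mixture) - 1) > 1e-9) {
    abort("'band_mixture' must be three non-negative weights summing to 1",
          class = "actibed_config_error")
  }
  structure(list(
    n_participants = check_count(n_participants, "n_participants", min = 1L),
    n_days = check_count(n_days, "n_days", min = 1L),
    epoch_length = 60L,
    tib_mean = check_number(tib_mean, "tib_mean", min = 0, strict_min = TRUE),
    tib_sd = check_number(tib_sd, "tib_sd", min = 0),
    tib_irregularity = check_number(tib_irregularity, "tib_irregularity",
                                    min = 0),
    bedtime_mean = clock_parse(bedtime_mean),
    nap_mean = check_number(nap_mean, "nap_mean", min = 0),
    activity_trait_sd = check_number(activity_trait_sd, "activity_trait_sd",
                                     min = 0),
    band_mixture = as.numeric(band_mixture),
    nonwear_gap_rate = check_number(nonwear_gap_rate, "nonwear_gap_rate",
                                    min = 0),
    inbed_counts_zero = { stopifnot_flag(inbed_counts_zero,
                                         "inbed_counts_zero")
                          inbed_counts_zero },
    seed = if (!is.null(seed)) check_count(seed, "seed", min = 0L),
    start_date = as.Date(start_date)
  ), class = "cohort_config")
}

# fixed generator internals (not exposed as dials)
.gen <- list(
  bed_person_sd = 45, bed_night_sd = 35,   # bedtime spread, minutes
  trait_tib_cor = 0.35,                    # low trait <-> long time in bed
  trait_coef = c(-1, 0.5, 1),              # trait load on regime logits
  low_zero_p = 0.2, low_shape = 1.2, low_mean = 850,
  high_shape = 1.5, high_mean_excess = 900,
  nap_p = 0.85, nap_shape = 1.6,
  gap_min = 32, gap_max = 75,              # shower gap length, minutes
  gap_window = c(510, 1200)                # gap start, minutes of day
)

draw_regime_counts <- function(regime, cfg) {
  n <- length(regime)
  out <- integer(n)
  i_low <- which(regime == 1L)
  if (length(i_low)) {
    z <- stats::runif(length(i_low)) < .gen$low_zero_p
    val <- round(stats::rgamma(length(i_low), shape = .gen$low_shape,
                               scale = .gen$low_mean / .gen$low_shape))
    out[i_low] <- ifelse(z, 0L, pmin(as.integer(val), 2302L))
  }
  i_mid <- which(regime == 2L)
  if (length(i_mid)) {
    out[i_mid] <- as.integer(2303L + floor(stats::runif(length(i_mid)) * 2697))
  }
  i_high <- which(regime == 3L)
  if (length(i_high)) {
    out[i_high] <- as.integer(5000L + round(stats::rgamma(
      length(i_high), shape = .gen$high_shape,
      scale = .gen$high_mean_excess / .gen$high_shape)))
  }
  out
}

generate_participant <- function(cfg, id) {
  n_min <- cfg$n_days * 1440L
  start <- as.POSIXct(paste(cfg$start_date), tz = "UTC")

  z_trait <- stats::rnorm(1)
  trait <- cfg$activity_trait_sd * z_trait
  rho <- .gen$trait_tib_cor
  z_tib <- -rho * z_trait + sqrt(1 - rho^2) * stats::rnorm(1)
  person_tib <- cfg$tib_mean + cfg$tib_sd * z_tib
  bed_off <- stats::rnorm(1, 0, .gen$bed_person_sd)

  # regime mixture for this participant
  w <- exp(log(cfg$band_mixture) + trait * .gen$trait_coef)
  w <- w / sum(w)

  counts <- integer(n_min)
  regime <- findInterval(stats::runif(n_min), cumsum(w)[1:2]) + 1L
  counts <- draw_regime_counts(regime, cfg)

  days <- vector("list", cfg$n_days)
  for (d in seq_len(cfg$n_days)) {
    date_d <- cfg$start_date + (d - 1L)
    day0 <- (d - 1L) * 1440L

    # nap(s): one block in the 12:00-16:00 window
    naps <- NULL
    if (cfg$nap_mean > 0 && stats::runif(1) < .gen$nap_p) {
      len <- round(stats::rgamma(1, shape = .gen$nap_shape,
                                 scale = (cfg$nap_mean / .gen$nap_p) /
                                   .gen$nap_shape))
      len <- min(len, 240L)
      if (len >= 5L) {
        nap_start <- 720L + floor(stats::runif(1) * max(1, 240L - len))
        idx <- (day0 + nap_start + 1L):(day0 + nap_start + len)
        idx <- idx[idx <= n_min]
        zr <- stats::runif(length(idx)) < 0.55
        counts[idx] <- ifelse(zr, 0L,
                              as.integer(10L + floor(stats::runif(
                                length(idx)) * 140)))
        base <- as.POSIXct(paste(date_d), tz = "UTC")
        naps <- data.frame(start = base + 60 * nap_start,
                           end = base + 60 * (nap_start + len))
      }
    }

    # shower / water-activity non-wear gaps: sustained exact zeros
    n_gap <- stats::rpois(1, cfg$nonwear_gap_rate)
    if (n_gap > 0L) {
      for (g in seq_len(n_gap)) {
        gl <- round(stats::runif(1, .gen$gap_min, .gen$gap_max))
        gs <- .gen$gap_window[1L] +
          floor(stats::runif(1) * (diff(.gen$gap_window) - gl))
        idx <- (day0 + gs + 1L):(day0 + gs + gl)
        counts[idx[idx <= n_min]] <- 0L
      }
    }

    # the night starting this evening
    bed_min <- round(cfg$bedtime_mean + bed_off +
                       stats::rnorm(1, 0, .gen$bed_night_sd))
    tib_d <- max(60, round(person_tib +
                             stats::rnorm(1, 0, cfg$tib_irregularity)))
    bed_abs <- day0 + bed_min
    rise_abs <- bed_abs + tib_d
    idx <- (bed_abs + 1L):rise_abs
    idx <- idx[idx >= 1L & idx <= n_min]
    if (length(idx)) {
      if (cfg$inbed_counts_zero) {
        counts[idx] <- 0L
      } else {
        rl <- stats::runif(length(idx)) < 0.9
        counts[idx] <- ifelse(rl, 0L,
                              as.integer(1L + floor(stats::runif(
                                length(idx)) * 99)))
      }
    }
    days[[d]] <- diary_day(date_d, start + 60 * bed_abs,
                           start + 60 * rise_abs, naps)
  }

  age <- min(99L, 75L + as.integer(floor(stats::rgamma(1, shape = 2.2,
                                                       scale = 3.0))))
  sex <- if (stats::runif(1) < 0.62) "female" else "male"
  sppb <- max(0L, min(12L, as.integer(round(
    10.3 + 0.66 * z_trait + stats::rnorm(1, 0, 1.6)))))

  list(
    participant_id = id,
    epochs = epoch_series(id, start, counts),
    diary = structure(days, participant_id = id),
    covariates = data.frame(participant_id = id, age = age,
                            sex = factor(sex, levels = c("male", "female")),
                            sppb_total = sppb)
  )
}

#' Generate a seeded synthetic cohort
#'
#' Produces `n_participants` tuples of (epoch series, diary, covariates).
#' Each epoch series spans `n_days` full days of 60-s epochs starting at
#' midnight of `start_date`; each diary holds one entry per night (the last
#' night's rise may fall beyond the recording and is clipped downstream).
#' Identical configuration and seed reproduce the cohort bit for bit; the
#' caller's RNG state is left untouched.
#'
#' @param config A [cohort_config()].
#' @return An object of class `actibed_cohort`: a list with element
#'   `participants` (each a list with `participant_id`, `epochs`, `diary`,
#'   `covariates`) and the `config` attached.
#' @examples
#' coh <- generate_cohort(cohort_config(n_participants = 2, seed = 42))
#' coh$participants[[1]]$epochs
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  ids <- sprintf("P%04d", seq_len(config$n_participants))
  participants <- with_seed(config$seed, {
    lapply(ids, function(id) generate_participant(config, id))
  })
  structure(list(participants = participants, config = config),
            class = "actibed_cohort")
}

#' @export
print.actibed_cohort <- function(x, ...) {
  cat(sprintf("<actibed_cohort> %d participants x %d days (seed %s)\n",
              length(x$participants), x$config$n_days,
              x$config$seed %||% "none"))
  invisible(x)
}

#' Covariate table of a synthetic cohort
#' @param cohort An `actibed_cohort`.
#' @return Data frame with `participant_id`, `age`, `sex`, `sppb_total`.
#' @export
cohort_covariates <- function(cohort) {
  out <- do.call(rbind, lapply(cohort$participants, `[[`, "covariates"))
  row.names(out) <- NULL
  out
}

#' Write a cohort to the epoch / diary / covariate CSV dialects
#' @param cohort An `actibed_cohort`.
#' @param dir Output directory (created if needed); writes `epochs.csv`,
#'   `diary.csv` and `covariates.csv`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ep <- file.path(dir, "epochs.csv")
  first <- TRUE
  for (p in cohort$participants) {
    df <- data.frame(participant_id = p$participant_id,
                     timestamp = ts_format(epoch_times(p$epochs)),
                     vm_cpm = p$epochs$counts)
    utils::write.table(df, ep, sep = ",", row.names = FALSE,
                       col.names = first, append = !first, quote = FALSE)
    first <- FALSE
  }
  dpath <- file.path(dir, "diary.csv")
  tmp <- tempfile(fileext = ".csv")
  dfs <- lapply(cohort$participants, function(p) {
    write_diary(p$diary, tmp, participant_id = p$participant_id)
    utils::read.csv(tmp, colClasses = "character")
  })
  all_cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (cc in setdiff(all_cols, names(d))) d[[cc]] <- ""
    d[all_cols]
  })
  utils::write.csv(do.call(rbind, dfs), dpath, row.names = FALSE,
                   quote = FALSE)
  unlink(tmp)
  write_covariates(cohort_covariates(cohort),
                   file.path(dir, "covariates.csv"))
  invisible(dir)
}

#' Simulate analysis rows from a known multinomial logit
#'
#' Draws each participant's time-in-bed category from the baseline-category
#' logit implied by `true_betas` (reference UTIB), emitting the standardised
#' exposure and covariates so the model can be refit and compared with the
#' truth. All non-intercept design columns are generated iid standard
#' normal.
#'
#' @param true_betas Coefficients for the two non-reference outcomes: a
#'   2-row matrix with rownames `STIB`, `RTIB` and named columns including
#'   `(Intercept)`, or a list with elements `STIB` and `RTIB` of identically
#'   named vectors.
#' @param config A [cohort_config()]; only `n_participants` and `seed` are
#'   used.
#' @return Data frame with `tib_category` and one column per non-intercept
#'   term, with the true probability matrix attached as attribute
#'   `true_probs` and `true_betas` as attribute `true_betas`.
#' @examples
#' b <- rbind(STIB = c("(Intercept)" = 0, exposure = -0.3),
#'            RTIB = c("(Intercept)" = 0, exposure = -0.8))
#' d <- generate_from_logit(b, cohort_config(n_participants = 500, seed = 9))
#' table(d$tib_category)
#' @export
generate_from_logit <- function(true_betas, config = cohort_config()) {
  if (is.list(true_betas) && !is.matrix(true_betas)) {
    true_betas <- rbind(STIB = true_betas$STIB, RTIB = true_betas$RTIB)
  }
  if (!is.matrix(true_betas) || nrow(true_betas) != 2L ||
      is.null(colnames(true_betas)) ||
      !"(Intercept)" %in% colnames(true_betas)) {
    abort("true_betas must be a 2 x p matrix (rows STIB, RTIB) with named ",
          "columns including (Intercept)", class = "actibed_config_error")
  }
  rownames(true_betas) <- c("STIB", "RTIB")
  terms <- setdiff(colnames(true_betas), "(Intercept)")
  n <- config$n_participants
  with_seed(config$seed, {
    Xs <- matrix(stats::rnorm(n * length(terms)), n,
                 dimnames = list(NULL, terms))
    X <- cbind(`(Intercept)` = 1, Xs)
    eta <- X %*% t(true_betas[, colnames(X), drop = FALSE])
    m <- pmax(0, apply(eta, 1, max))
    denom <- exp(-m) + exp(eta[, 1] - m) + exp(eta[, 2] - m)
    P <- cbind(UTIB = exp(-m), STIB = exp(eta[, 1] - m),
               RTIB = exp(eta[, 2] - m)) / denom
    stopifnot(all(abs(rowSums(P) - 1) < 1e-9))   # must be impossible
    u <- stats::runif(n)
    cat_idx <- 1L + (u > P[, 1]) + (u > P[, 1] + P[, 2])
    out <- data.frame(tib_category = factor(
      c("UTIB", "STIB", "RTIB")[cat_idx],
      levels = c("UTIB", "STIB", "RTIB")))
    out <- cbind(out, as.data.frame(Xs))
    attr(out, "true_probs") <- P
    attr(out, "true_betas") <- true_betas
    out
  })
}
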