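# End-to-end orchestration: simulate (or read) -> mask -> summarise ->
# categorise -> model -> sensitivity, with exclusion logging and a
# deterministic report bundle of plain tables.

#' Pipeline configuration
#'
#' All defaults equal the study constants, so an empty override set
#' reproduces the canonical pipeline. In simulate mode the cohort comes from
#' [generate_cohort()]; in file mode `paths` must name `epochs`, `diary` and
#' `covariates` CSVs in the package dialects.
#'
#' @param cohort A [cohort_config()] for simulate mode.
#' @param paths Optional named list/vector with `epochs`, `diary`,
#'   `covariates` file paths (file mode).
#' @param bands An [intensity_bands()] override.
#' @param tib A [tib_rule()] override.
#' @param nonwear A [nonwear_params()] override.
#' @param exposures Character vector of model exposures to fit.
#' @param seed Seed for simulate mode; overrides `cohort$seed` when given.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), paths = NULL,
                            bands = intensity_bands(), tib = tib_rule(),
                            nonwear = nonwear_params(),
                            exposures = c("avg_cpm", "pct_mid", "pct_high",
                                          "highly_sedentary"),
                            seed = NULL) {
  if (!is.null(paths)) {
    paths <- as.list(paths)
    need <- c("epochs", "diary", "covariates")
    if (!all(need %in% names(paths))) {
      abort("paths must name epochs, diary and covariates files",
            class = "actibed_config_error")
    }
    missing <- !vapply(paths[need], file.exists, TRUE)
    if (any(missing)) {
      abort("input file not found: ",
            paste(unlist(paths[need][missing]), collapse = ", "),
            class = "actibed_config_error")
    }
  }
  if (!is.null(seed)) cohort$seed <- check_count(seed, "seed", min = 0L)
  structure(list(cohort = cohort, paths = paths, bands = bands, tib = tib,
                 nonwear = nonwear, exposures = exposures),
            class = "pipeline_config")
}

# one participant through masking, summaries, exposure and TIB category;
# returns either an analysis row or an exclusion record
process_participant <- function(p, bands, nonwear, tib) {
  nw <- detect_nonwear(p$epochs, nonwear)
  mask <- apply_masks(p$epochs, nw, p$diary)
  daily <- daily_summary(p$epochs, mask, bands)
  expo <- participant_exposure(daily, p$diary, bands)
  if (inherits(expo, "participant_excluded")) {
    return(list(excluded = data.frame(participant_id = p$participant_id,
                                      stage = "validity",
                                      reason = expo$reason)))
  }
  tb <- tib_from_diary(p$diary, tib)
  row <- cbind(data.frame(participant_id = p$participant_id), expo,
               data.frame(tib_category = tb$category,
                          median_nightly_tib_min = tb$median_tib,
                          diary_nights = tb$nights))
  list(row = row, daily = daily)
}

#' Build the analysis table for a cohort
#'
#' Runs every participant through non-wear detection, diary masking, daily
#' summaries, the validity filter, pooled exposures and time-in-bed
#' categorisation, then joins covariates and assigns cohort tertiles for
#' the three activity exposures.
#'
#' @param cohort An `actibed_cohort` (or list of participant lists with
#'   `participant_id`, `epochs`, `diary`, `covariates`).
#' @param bands,nonwear,tib Stage parameter objects.
#' @return A list with `table` (one row per retained participant) and
#'   `exclusions` (participant_id, stage, reason).
#' @export
build_analysis_table <- function(cohort, bands = intensity_bands(),
                                 nonwear = nonwear_params(),
                                 tib = tib_rule()) {
  parts <- if (!is.null(cohort$participants)) cohort$participants else cohort
  if (!length(parts)) {
    abort("empty cohort: nothing to process", class = "actibed_domain_error")
  }
  rows <- list(); excl <- list()
  for (p in parts) {
    res <- tryCatch(process_participant(p, bands, nonwear, tib),
                    actibed_error = function(e) {
      abort("stage failure for participant ", p$participant_id, ": ",
            conditionMessage(e), class = "actibed_pipeline_error")
    })
    if (!is.null(res$excluded)) excl[[length(excl) + 1L]] <- res$excluded
    else {
      row <- res$row
      cov <- p$covariates
      row$age <- cov$age; row$sex <- cov$sex
      row$sppb_total <- cov$sppb_total
      rows[[length(rows) + 1L]] <- row
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(tab) && nrow(tab) >= 3L) {
    tab$avg_cpm_tertile <- tertile_assign(tab$avg_cpm)
    tab$pct_mid_tertile <- tertile_assign(tab$pct_mid)
    tab$pct_high_tertile <- tertile_assign(tab$pct_high)
  }
  if (!is.null(tab)) row.names(tab) <- NULL
  excl <- if (length(excl)) do.call(rbind, excl)
          else data.frame(participant_id = character(),
                          stage = character(), reason = character())
  list(table = tab, exclusions = excl)
}

med_iqr <- function(x) sprintf("%.1f (%.1f)", stats::median(x),
                               stats::IQR(x))

# descriptive summary by TIB category (median (IQR) / percentages)
describe_by_category <- function(tab) {
  groups <- split(tab, tab$tib_category)
  out <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    if (!nrow(d)) return(NULL)
    data.frame(
      tib_category = g, n = nrow(d),
      age = med_iqr(d$age),
      women_pct = round(100 * mean(d$sex == "female"), 1),
      tib_per_night = med_iqr(d$median_nightly_tib_min),
      nap_min_per_day = med_iqr(d$avg_nap_minutes),
      sppb_total = med_iqr(d$sppb_total),
      wear_min_per_day = med_iqr(d$wear_minutes_per_day),
      avg_cpm = med_iqr(d$avg_cpm),
      highly_sedentary_pct = round(100 * mean(d$highly_sedentary), 1),
      pct_sb = med_iqr(d$pct_sb),
      pct_mid = med_iqr(d$pct_mid),
      pct_high = med_iqr(d$pct_high))
  })
  do.call(rbind, out)
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a cohort, builds the analysis table with exclusion
#' logging, produces a descriptive summary by time-in-bed category, fits
#' the configured study models with relative risk ratios and predicted
#' probabilities, and runs the fixed-window sensitivity analysis. All
#' report components are plain data frames, so a rerun with the same
#' configuration and seed is identical object for object.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `actibed_report` with elements `analysis_table`,
#'   `exclusions`, `flow` (participants entering/retained), `descriptives`,
#'   `models`, `rrr` (stacked exposure RRR rows), `probabilities`,
#'   `contrasts`, `sensitivity` and `n`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$paths)) {
    cohort <- generate_cohort(config$cohort)
  } else {
    eps <- read_epochs_all(config$paths$epochs)
    dia <- read_diary_all(config$paths$diary)
    cov <- read_covariates(config$paths$covariates)
    cohort <- list(participants = lapply(names(eps), function(id) {
      list(participant_id = id, epochs = eps[[id]],
           diary = dia[[id]],
           covariates = cov[cov$participant_id == id, , drop = FALSE])
    }))
  }
  built <- build_analysis_table(cohort, config$bands, config$nonwear,
                                config$tib)
  tab <- built$table
  if (is.null(tab) || nrow(tab) < 3L) {
    abort("fewer than 3 retained participants; cannot continue",
          class = "actibed_pipeline_error")
  }
  n_in <- length(cohort$participants)
  flow <- data.frame(
    stage = c("entered", "excluded_validity", "retained"),
    n = c(n_in, nrow(built$exclusions), nrow(tab)))

  models <- list(); rrr_rows <- list(); prob_rows <- list()
  contrast_rows <- list()
  failures <- data.frame(exposure = character(), reason = character())
  for (expo in config$exposures) {
    m <- tryCatch(fit_tib_model(tab, expo), actibed_model_error = function(e) e)
    if (inherits(m, "condition")) {
      # small cohorts can separate perfectly for one exposure; record the
      # failure deterministically and keep the remaining models
      failures <- rbind(failures, data.frame(
        exposure = expo, reason = conditionMessage(m)))
      next
    }
    models[[expo]] <- list(exposure = expo, model = m$model, n = m$n,
                           rrr = m$rrr, rrr_table = m$rrr_table,
                           overall_p = m$overall_p)
    rr <- m$rrr
    rr$exposure <- expo
    rr$overall_p <- m$overall_p
    rrr_rows[[expo]] <- rr
    pp <- predicted_probabilities(m$fit, m$exposure_column)
    pp$exposure <- expo
    prob_rows[[expo]] <- pp
    lv <- levels(m$fit$model[[m$exposure_column]])
    ct <- probability_contrast(m$fit, m$exposure_column,
                               lv[length(lv)], lv[1L])
    ct$exposure <- expo
    ct$contrast_levels <- paste(lv[length(lv)], "vs", lv[1L])
    contrast_rows[[expo]] <- ct
  }

  # sensitivity on the retained participants only
  keep <- vapply(cohort$participants,
                 function(p) p$participant_id %in% tab$participant_id, TRUE)
  sens <- sensitivity_analysis(cohort$participants[keep], config$bands,
                               config$nonwear)

  structure(list(
    analysis_table = tab,
    exclusions = built$exclusions,
    flow = flow,
    descriptives = describe_by_category(tab),
    models = models,
    rrr = { r <- do.call(rbind, rrr_rows); row.names(r) <- NULL; r },
    probabilities = { r <- do.call(rbind, prob_rows); row.names(r) <- NULL; r },
    contrasts = { r <- do.call(rbind, contrast_rows); row.names(r) <- NULL; r },
    sensitivity = sens,
    model_failures = failures,
    n = nrow(tab),
    config = config
  ), class = "actibed_report")
}

#' @export
print.actibed_report <- function(x, ...) {
  cat("=== actibed pipeline report ===\n")
  cat(sprintf("Participants: %d entered, %d excluded, %d retained\n",
              x$flow$n[1], x$flow$n[2], x$flow$n[3]))
  cat("\nTime-in-bed categories:\n")
  print(table(x$analysis_table$tib_category))
  cat("\nDescriptives by category:\n")
  print(x$descriptives[c("tib_category", "n", "tib_per_night", "avg_cpm",
                         "pct_sb", "highly_sedentary_pct")],
        row.names = FALSE)
  cat("\nExposure relative risk ratios (reference UTIB, low/not exposed):\n")
  rr <- x$rrr[c("exposure", "outcome", "term", "rrr", "rrr_lower",
                "rrr_upper", "p_value", "overall_p")]
  rr[-(1:3)] <- lapply(rr[-(1:3)], signif, 3)
  print(rr, row.names = FALSE)
  cat("\n")
  print(x$sensitivity)
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' Writes `analysis_table.csv`, `exclusions.csv`, `flow.csv`,
#' `descriptives.csv`, `rrr.csv`, `probabilities.csv`, `contrasts.csv`,
#' `sensitivity.csv` and a machine-readable `report.json`. Byte-identical
#' for identical reports.
#'
#' @param report An `actibed_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) utils::write.csv(
    df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  wr(report$analysis_table, "analysis_table.csv")
  wr(report$exclusions, "exclusions.csv")
  wr(report$flow, "flow.csv")
  wr(report$descriptives, "descriptives.csv")
  wr(report$rrr, "rrr.csv")
  wr(report$probabilities, "probabilities.csv")
  wr(report$contrasts, "contrasts.csv")
  wr(report$sensitivity$by_participant, "sensitivity.csv")
  json <- list(
    n = report$n, flow = report$flow,
    tib_categories = as.list(table(report$analysis_table$tib_category)),
    rrr = report$rrr, contrasts = report$contrasts,
    sensitivity_inflation = report$sensitivity$inflation)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
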