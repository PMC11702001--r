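#' Run the full sudden-gain pipeline
#'
#' Orchestrates simulate (or load) -> inclusion filter -> detection ->
#' cohort summary -> around-gain extraction -> outcome and process models,
#' and writes the report bundle to `out_dir`:
#'
#' * `gains.csv` — all detected gains with reversal flags and the primary
#'   marker;
#' * `summary.json` — cohort summary (occurrence rate, counts, magnitude,
#'   reversals, pre-gain histogram) plus the inclusion report and the
#'   duration comparison;
#' * `outcome_model.csv` — unadjusted group means/SDs per timepoint and the
#'   covariate-adjusted group differences;
#' * `contrasts.csv` — consecutive around-gain contrasts for every measure;
#' * `figures/*.pdf` — mean LSAS around the gain, pre-gain-week histogram,
#'   group trajectories, and the process panel.
#'
#' Every CSV carries header comment lines recording the package version,
#' seed, and detection criteria, so a report is auditable from its files
#' alone. Outputs are a pure function of (inputs, config, seed).
#'
#' @param out_dir Output directory (created if needed).
#' @param cohort Optional validated long cohort tibble; when `NULL` a cohort
#'   is simulated from `config`.
#' @param endpoints Optional endpoints tibble (`participant_id`,
#'   `lsas_post`, `lsas_fu3m`); simulated cohorts supply their own. When
#'   absent for a supplied cohort, post-intervention defaults to the last
#'   observed weekly LSAS and follow-up is missing.
#' @param config [sim_config()] used when simulating.
#' @param criteria [gain_criteria()] for detection.
#' @param min_lsas_points Inclusion threshold (default 8).
#' @param seed Optional seed; overrides `config$seed`.
#' @param figures Write figure PDFs (default TRUE).
#' @param clip_week Cohort-level figures clip the x axis here (default 14,
#'   a typical median end of treatment).
#' @return Invisibly, a list with the computed objects (`included`,
#'   `excluded`, `report`, `gains`, `summary`, `around`, `outcome_fit`,
#'   `contrasts`, `duration_test`) and `paths` of the written files.
#' @export
run_pipeline <- function(out_dir, cohort = NULL, endpoints = NULL,
                         config = sim_config(), criteria = gain_criteria(),
                         min_lsas_points = 8, seed = NULL, figures = TRUE,
                         clip_week = 14) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(seed)) config$seed <- as.integer(seed)

  if (is.null(cohort)) {
    sim <- simulate_cohort(config)
    cohort <- sim$cohort
    endpoints <- endpoints %||% sim$endpoints
    inform(paste0("simulated ", config$n_participants, " participants (seed ",
                  config$seed %||% "unset", ")"))
  }

  filt <- apply_inclusion_filter(cohort, min_lsas_points)
  inform(paste0("inclusion filter: ", filt$report$n_included, " of ",
                filt$report$n_total, " participants retained"))

  gains <- detect_sudden_gains(filt$included, criteria)
  summ <- summarize_gains(gains, filt$included)
  inform(paste0("detected ", summ$n_gains_total, " gains in ",
                summ$n_with_gain, " participants (",
                summ$occurrence_rate_pct, "%), ",
                summ$n_reversals, " reversed"))

  meta <- cohort_metadata(filt$included)
  duration_test <- if (summ$n_with_gain > 0 &&
                       summ$n_with_gain < summ$n_participants) {
    gain_ids <- unique(gains$participant_id)
    compare_duration(meta$n_weeks[meta$participant_id %in% gain_ids],
                     meta$n_weeks[!meta$participant_id %in% gain_ids])
  } else NULL

  primary <- dplyr::filter(gains, .data$is_primary)
  around <- if (nrow(primary)) {
    extract_around_gain(filt$included, primary)
  } else NULL
  contrasts <- if (!is.null(around)) process_contrast_table(around) else NULL

  outcome_fit <- NULL
  if (!is.null(endpoints) && nrow(primary)) {
    ep <- endpoints |>
      dplyr::filter(.data$participant_id %in% meta$participant_id) |>
      dplyr::mutate(sg = .data$participant_id %in% primary$participant_id)
    if (!"baseline_lsas" %in% names(ep)) {
      ep <- dplyr::left_join(
        ep, dplyr::select(meta, "participant_id", "baseline_lsas"),
        by = "participant_id"
      )
    }
    outcome_fit <- tryCatch(fit_outcome_model(ep), error = function(e) {
      warn(paste0("outcome model not fitted: ", conditionMessage(e)))
      NULL
    })
  }

  stamp <- c(
    paste0("# suddenstep ", as.character(utils::packageVersion("suddenstep"))),
    paste0("# seed: ", config$seed %||% "unset"),
    paste0("# criteria: cutoff=", criteria$cutoff, " pct=", criteria$pct,
           " stability_alpha=", criteria$stability_alpha,
           " min_window=", criteria$min_window,
           " min_lsas_points=", min_lsas_points)
  )
  paths <- list(
    gains = file.path(out_dir, "gains.csv"),
    summary = file.path(out_dir, "summary.json"),
    outcome = file.path(out_dir, "outcome_model.csv"),
    contrasts = file.path(out_dir, "contrasts.csv")
  )

  write_stamped_csv(gains, paths$gains, stamp)

  jsonlite::write_json(list(
    package = "suddenstep",
    version = as.character(utils::packageVersion("suddenstep")),
    seed = config$seed,
    criteria = unclass(criteria),
    inclusion = filt$report,
    summary = list(
      n_participants = summ$n_participants,
      n_with_gain = summ$n_with_gain,
      occurrence_rate_pct = summ$occurrence_rate_pct,
      n_gains_total = summ$n_gains_total,
      gains_per_participant = summ$gains_per_participant,
      magnitude_mean = summ$magnitude_mean,
      magnitude_sd = summ$magnitude_sd,
      n_reversals = summ$n_reversals,
      pregain_week_histogram = summ$pregain_week_histogram
    ),
    duration_test = duration_test
  ), paths$summary, auto_unbox = TRUE, digits = NA, pretty = TRUE,
     na = "null")

  if (!is.null(outcome_fit)) {
    out_tbl <- dplyr::bind_rows(
      dplyr::mutate(outcome_fit$cell_stats, block = "unadjusted_cells"),
      dplyr::mutate(outcome_fit$comparisons, block = "adjusted_differences")
    )
    write_stamped_csv(out_tbl, paths$outcome, stamp)
  }
  if (!is.null(contrasts)) write_stamped_csv(contrasts, paths$contrasts, stamp)

  if (figures) {
    figdir <- file.path(out_dir, "figures")
    dir.create(figdir, showWarnings = FALSE)
    save_quiet <- function(name, plot) {
      ggplot2::ggsave(file.path(figdir, name), plot, device = "pdf",
                      width = 7, height = 5)
    }
    if (!is.null(around)) save_quiet("lsas_around_gain.pdf",
                                     plot_gain_profile(around))
    if (nrow(gains)) save_quiet("pregain_week_histogram.pdf",
                                plot_pregain_histogram(gains))
    save_quiet("group_trajectories.pdf",
               plot_group_trajectories(filt$included, gains,
                                       clip_week = clip_week))
    if (!is.null(around)) save_quiet("process_panel.pdf",
                                     plot_process_panel(around))
  }

  invisible(list(
    included = filt$included, excluded = filt$excluded,
    report = filt$report, gains = gains, summary = summ, around = around,
    outcome_fit = outcome_fit, contrasts = contrasts,
    duration_test = duration_test, paths = paths
  ))
}

# CSV with leading '#' comment lines recording provenance
write_stamped_csv <- function(df, path, stamp) {
  body <- sub("\n+$", "", readr::format_csv(df, na = ""))
  writeLines(c(stamp, body), path)
  invisible(path)
}
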