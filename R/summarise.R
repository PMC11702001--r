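#' Cohort-level sudden-gain summary
#'
#' Aggregates a cohort's detected gains: how many participants gained at
#' least once (the occurrence rate), how gains distribute across
#' participants, the magnitude of all gains (not only primary ones), how
#' many reversed, and the histogram of pre-gain weeks.
#'
#' The occurrence rate is reported as an integer percentage, rounded half
#' away from zero (so 39.5% reports as 40).
#'
#' @param gains Output of [detect_sudden_gains()] on the included cohort.
#' @param cohort The included cohort the gains were computed on (sets the
#'   participant denominator).
#' @return An object of class `sg_summary`: a list with `n_participants`,
#'   `n_with_gain`, `occurrence_rate_pct`, `n_gains_total`,
#'   `gains_per_participant` (tibble `n_gains`, `n_participants`),
#'   `magnitude_mean`, `magnitude_sd`, `n_reversals`, and
#'   `pregain_week_histogram` (tibble `n`, `count`).
#' @export
summarize_gains <- function(gains, cohort) {
  ids <- unique(cohort$participant_id)
  n_participants <- length(ids)
  n_with_gain <- dplyr::n_distinct(gains$participant_id)
  per <- if (nrow(gains)) {
    gains |>
      dplyr::count(.data$participant_id, name = "n_gains") |>
      dplyr::count(.data$n_gains, name = "n_participants") |>
      dplyr::arrange(.data$n_gains)
  } else {
    tibble::tibble(n_gains = integer(), n_participants = integer())
  }
  hist <- if (nrow(gains)) {
    dplyr::arrange(dplyr::count(gains, .data$n, name = "count"), .data$n)
  } else {
    tibble::tibble(n = integer(), count = integer())
  }
  structure(list(
    n_participants = n_participants,
    n_with_gain = n_with_gain,
    occurrence_rate_pct = round_half_up(
      if (n_participants) 100 * n_with_gain / n_participants else 0
    ),
    n_gains_total = nrow(gains),
    gains_per_participant = per,
    magnitude_mean = if (nrow(gains)) mean(gains$magnitude) else NA_real_,
    magnitude_sd = if (nrow(gains) > 1) sd(gains$magnitude) else NA_real_,
    n_reversals = sum(gains$reversed),
    pregain_week_histogram = hist
  ), class = "sg_summary")
}

#' @export
print.sg_summary <- function(x, ...) {
  cat("Sudden-gain cohort summary\n",
      "  participants:        ", x$n_participants, "\n",
      "  with >= 1 gain:      ", x$n_with_gain,
      " (", x$occurrence_rate_pct, "%)\n",
      "  total gains:         ", x$n_gains_total, "\n",
      "  magnitude mean (SD): ",
      round(x$magnitude_mean, 2), " (", round(x$magnitude_sd, 2), ")\n",
      "  reversals:           ", x$n_reversals, "\n", sep = "")
  invisible(x)
}

#' @export
glance.sg_summary <- function(x, ...) {
  tibble::tibble(
    n_participants = x$n_participants,
    n_with_gain = x$n_with_gain,
    occurrence_rate_pct = x$occurrence_rate_pct,
    n_gains_total = x$n_gains_total,
    magnitude_mean = x$magnitude_mean,
    magnitude_sd = x$magnitude_sd,
    n_reversals = x$n_reversals
  )
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Compare treatment duration between gainers and non-gainers
#'
#' Two-sided Mann-Whitney U test (via [stats::wilcox.test()], exact when
#' feasible, otherwise normal approximation with tie and continuity
#' correction) on the number of treatment weeks, to probe whether sudden
#' gains are simply a by-product of longer treatment.
#'
#' @param sg_weeks Weeks of treatment for participants with a gain.
#' @param nosg_weeks Weeks of treatment for participants without.
#' @return One-row tibble: `u_statistic` (U for the gain group), `p_value`,
#'   `mean_sg`, `mean_nosg`, `n_sg`, `n_nosg`.
#' @export
compare_duration <- function(sg_weeks, nosg_weeks) {
  if (!length(sg_weeks)) abort("the gain group is empty")
  if (!length(nosg_weeks)) abort("the no-gain group is empty")
  wt <- suppressWarnings(wilcox.test(sg_weeks, nosg_weeks, exact = NULL))
  tibble::tibble(
    u_statistic = unname(wt$statistic),
    p_value = wt$p.value,
    mean_sg = mean(sg_weeks),
    mean_nosg = mean(nosg_weeks),
    n_sg = length(sg_weeks),
    n_nosg = length(nosg_weeks)
  )
}
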