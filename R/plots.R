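mean_se_tbl <- function(d, by) {
  d |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
}

#' Mean LSAS around the gain
#'
#' Line plot of the mean (+/- 1 SE) LSAS score at the six timepoints around
#' participants' primary sudden gains.
#'
#' @param around_long Output of [extract_around_gain()] including `lsas`.
#' @return A ggplot.
#' @export
plot_gain_profile <- function(around_long) {
  d <- mean_se_tbl(dplyr::filter(around_long, .data$measure == "lsas"),
                   "timepoint")
  ggplot2::ggplot(d, ggplot2::aes(.data$timepoint, .data$mean, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::labs(x = "Timepoint around the sudden gain", y = "Mean LSAS",
                  title = "LSAS around sudden gains") +
    ggplot2::theme_minimal()
}

#' Histogram of pre-gain weeks
#'
#' @param gains [detect_sudden_gains()] output (all gains, not only primary).
#' @return A ggplot.
#' @export
plot_pregain_histogram <- function(gains) {
  ggplot2::ggplot(gains, ggplot2::aes(factor(.data$n))) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "Pre-gain week (n)", y = "Number of sudden gains",
                  title = "When sudden gains occur") +
    ggplot2::theme_minimal()
}

#' Mean weekly LSAS trajectories by gain status
#'
#' @param cohort Included long cohort tibble.
#' @param gains [detect_sudden_gains()] output (defines the gain group).
#' @param clip_week Clip the x axis at this week (NULL = full length).
#' @return A ggplot.
#' @export
plot_group_trajectories <- function(cohort, gains, clip_week = 14) {
  gain_ids <- unique(gains$participant_id)
  d <- cohort |>
    dplyr::filter(.data$measure == "lsas") |>
    dplyr::mutate(group = ifelse(.data$participant_id %in% gain_ids,
                                 "Sudden gain", "No sudden gain"))
  if (!is.null(clip_week)) d <- dplyr::filter(d, .data$week <= clip_week)
  d <- mean_se_tbl(d, c("group", "week"))
  ggplot2::ggplot(d, ggplot2::aes(.data$week, .data$mean,
                                  colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Week", y = "Mean LSAS", colour = NULL,
                  title = "Symptom trajectories by sudden-gain status") +
    ggplot2::theme_minimal()
}

#' Process-measure panel around the gain
#'
#' Faceted mean (+/- 1 SE) profiles of each process measure across the six
#' around-gain timepoints.
#'
#' @param around_long Output of [extract_around_gain()].
#' @param measures Measures to show; defaults to all present.
#' @return A ggplot.
#' @export
plot_process_panel <- function(around_long,
                               measures = unique(around_long$measure)) {
  d <- mean_se_tbl(
    dplyr::filter(around_long, .data$measure %in% measures),
    c("measure", "timepoint")
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$timepoint, .data$mean, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "Timepoint around the sudden gain", y = "Mean score",
                  title = "Process measures around sudden gains") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sg_summary <- function(object, ...) {
  ggplot2::ggplot(object$pregain_week_histogram,
                  ggplot2::aes(factor(.data$n), .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Pre-gain week (n)", y = "Number of sudden gains") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sg_process_fit <- function(object, ...) {
  ggplot2::ggplot(object$cell_stats,
                  ggplot2::aes(.data$timepoint, .data$mean, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$sd / sqrt(.data$n),
      ymax = .data$mean + .data$sd / sqrt(.data$n)
    )) +
    ggplot2::labs(x = "Timepoint", y = object$measure) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sg_outcome_fit <- function(object, ...) {
  ggplot2::ggplot(object$cell_stats,
                  ggplot2::aes(.data$time, .data$mean, colour = .data$sg,
                               group = .data$sg)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$sd / sqrt(.data$n),
      ymax = .data$mean + .data$sd / sqrt(.data$n)
    )) +
    ggplot2::labs(x = NULL, y = "LSAS", colour = "Group") +
    ggplot2::theme_minimal()
}
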