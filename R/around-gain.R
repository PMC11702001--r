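sg_timepoint_levels <- c("n-2", "n-1", "n", "n+1", "n+2", "n+3")

#' Align measures to the gain timeline
#'
#' For every participant with a primary sudden gain, extracts each requested
#' measure at the six timepoints around the gain — offsets `n-2 .. n+3` in
#' absolute week arithmetic. Offsets that fall before week 1 or beyond the
#' participant's last recorded week, or whose value was simply not observed,
#' are emitted as missing rows (no interpolation, no "next available
#' observation" substitution). LSAS itself can be included as a measure to
#' model the gain's own shape.
#'
#' @param cohort Validated long cohort tibble.
#' @param primary_gains Tibble with one row per participant, columns
#'   `participant_id` and `n` (e.g. [detect_sudden_gains()] output filtered
#'   to `is_primary`).
#' @param measures Character vector of measure names to extract; defaults to
#'   every measure present in `cohort`.
#' @return Tibble `participant_id`, `measure`, `timepoint` (factor with
#'   levels `n-2 .. n+3`), `week` (absolute week, `NA` when off the edge),
#'   `value`; ordered by participant, measure, timepoint.
#' @export
extract_around_gain <- function(cohort, primary_gains,
                                measures = unique(cohort$measure)) {
  if (anyDuplicated(primary_gains$participant_id)) {
    abort("primary_gains must have exactly one row per participant")
  }
  absent <- setdiff(primary_gains$participant_id, cohort$participant_id)
  if (length(absent)) {
    abort(paste0("participant(s) in gains but absent from cohort: ",
                 paste(absent, collapse = ", ")))
  }

  last_week <- cohort |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(last_week = max(.data$week), .groups = "drop")

  grid <- primary_gains |>
    dplyr::select("participant_id", "n") |>
    tidyr::expand_grid(measure = measures, offset = -2:3) |>
    dplyr::left_join(last_week, by = "participant_id") |>
    dplyr::mutate(
      timepoint = factor(sg_timepoint_levels[.data$offset + 3L],
                         levels = sg_timepoint_levels),
      week_abs = .data$n + .data$offset,
      week = dplyr::if_else(
        .data$week_abs >= 1L & .data$week_abs <= .data$last_week,
        as.integer(.data$week_abs), NA_integer_
      )
    )

  grid |>
    dplyr::left_join(
      dplyr::select(cohort, "participant_id", "measure", "week", "value"),
      by = c("participant_id", "measure", "week")
    ) |>
    dplyr::select("participant_id", "measure", "timepoint", "week", "value") |>
    dplyr::arrange(.data$participant_id, .data$measure, .data$timepoint)
}
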