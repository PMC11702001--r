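#' Apply the minimum-data inclusion filter
#'
#' Participants contributing fewer than `min_lsas_points` non-missing weekly
#' LSAS values are excluded from sudden-gain analysis: too few datapoints
#' make the three-criterion classification (which needs pre- and post-gain
#' windows) unreliable. The default of 8 retains a participant with exactly
#' 8 observed LSAS values. Weeks with a missing LSAS do not count, so a long
#' but sparsely measured trajectory can still be excluded.
#'
#' @param cohort Validated long cohort tibble.
#' @param min_lsas_points Minimum number of non-missing LSAS values
#'   (default 8).
#' @return A list with elements `included` and `excluded` (long cohort
#'   tibbles partitioning the input) and `report`, a one-row tibble with
#'   `n_total`, `n_included`, `n_excluded`, `min_lsas_points`.
#' @export
#' @examples
#' cohort <- tibble::tibble(
#'   participant_id = rep(c("a", "b"), each = 9),
#'   week = rep(1:9, 2), measure = "lsas",
#'   value = c(80:72, 80, 79, NA, NA, 76, NA, 74, NA, 72)
#' )
#' apply_inclusion_filter(cohort, min_lsas_points = 8)$report
apply_inclusion_filter <- function(cohort, min_lsas_points = 8) {
  stopifnot(min_lsas_points >= 1)
  if (nrow(cohort) == 0) {
    empty <- cohort
    return(list(
      included = empty, excluded = empty,
      report = tibble::tibble(n_total = 0L, n_included = 0L, n_excluded = 0L,
                              min_lsas_points = min_lsas_points)
    ))
  }
  meta <- cohort_metadata(cohort)
  keep_ids <- meta$participant_id[meta$n_lsas_points >= min_lsas_points]
  included <- dplyr::filter(cohort, .data$participant_id %in% keep_ids)
  excluded <- dplyr::filter(cohort, !.data$participant_id %in% keep_ids)
  list(
    included = included,
    excluded = excluded,
    report = tibble::tibble(
      n_total = nrow(meta),
      n_included = length(keep_ids),
      n_excluded = nrow(meta) - length(keep_ids),
      min_lsas_points = min_lsas_points
    )
  )
}
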