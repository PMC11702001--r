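#' Enumerate candidate gain intervals in one trajectory
#'
#' A week pair `(n, n + 1)` is a candidate interval when both LSAS values
#' are observed and both the pre window (weeks `n-2..n`) and the post window
#' (weeks `n+1..n+3`) contain at least `min_window` observed values. Windows
#' at the trajectory edges use whatever of the three slots exist, so week 1
#' is never a candidate pre-gain week (its pre window has a single slot) and
#' neither is the final week pair's `n` when fewer than two post values
#' exist. An interval spanning a missing week is never a candidate:
#' "consecutive" means adjacent week indices with both values observed.
#'
#' @param lsas Numeric vector of weekly LSAS values indexed by week
#'   (`lsas[w]` is week `w`); `NA` = missing.
#' @param criteria A [gain_criteria()] object.
#' @return Tibble with one row per candidate: `n`, `score_n`, `score_n1`,
#'   `n_pre`, `n_post` (observed window sizes).
#' @export
#' @examples
#' enumerate_candidates(c(80, 78, 76, 74, 50, 48, 46, 44))
enumerate_candidates <- function(lsas, criteria = gain_criteria()) {
  lsas <- as_lsas_vector(lsas)
  W <- length(lsas)
  rows <- list()
  if (W >= 2) {
    for (n in seq_len(W - 1L)) {
      s_n <- lsas[n]
      s_n1 <- lsas[n + 1L]
      if (is.na(s_n) || is.na(s_n1)) next
      pre <- lsas[max(1L, n - 2L):n]
      post <- lsas[(n + 1L):min(W, n + 3L)]
      n_pre <- sum(!is.na(pre))
      n_post <- sum(!is.na(post))
      if (n_pre < criteria$min_window || n_post < criteria$min_window) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n = n, score_n = s_n, score_n1 = s_n1,
        n_pre = n_pre, n_post = n_post
      )
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(n = integer(), score_n = double(),
                          score_n1 = double(), n_pre = integer(),
                          n_post = integer()))
  }
  dplyr::bind_rows(rows)
}

#' Detect sudden gains in a single trajectory
#'
#' Applies the three criteria (see [gain_criteria()]) to every candidate
#' interval and flags reversals. All qualifying intervals are returned, so a
#' participant can contribute more than one gain; use
#' [select_primary_gain()] to pick the one that enters group analyses.
#'
#' @inheritParams enumerate_candidates
#' @return Tibble ordered by `n` with columns `n`, `score_n`, `score_n1`,
#'   `magnitude`, `reversed`, `reversal_week` (`NA` if never reversed).
#' @export
#' @examples
#' x <- c(80, 60, 60, 60, 40, 40, 40, 38)
#' detect_gains(x) # one gain at n = 4, magnitude 20
detect_gains <- function(lsas, criteria = gain_criteria()) {
  lsas <- as_lsas_vector(lsas)
  cand <- enumerate_candidates(lsas, criteria)
  W <- length(lsas)
  out <- empty_gain_rows()
  for (i in seq_len(nrow(cand))) {
    n <- cand$n[i]
    s_n <- cand$score_n[i]
    s_n1 <- cand$score_n1[i]
    if (!((s_n - s_n1) >= criteria$cutoff)) next
    if (s_n <= 0 || !((s_n - s_n1) >= criteria$pct * s_n)) next
    pre <- lsas[max(1L, n - 2L):n]
    post <- lsas[(n + 1L):min(W, n + 3L)]
    pre <- pre[!is.na(pre)]
    post <- post[!is.na(post)]
    crit <- critical_value(length(pre), length(post), criteria$stability_alpha)
    if (!((mean(pre) - mean(post)) > crit * pooled_window_sd(pre, post))) next
    magnitude <- s_n - s_n1
    later_weeks <- if (n + 2L <= W) (n + 2L):W else integer()
    rev <- detect_reversal(s_n1, magnitude, lsas[later_weeks], later_weeks)
    out <- dplyr::bind_rows(out, tibble::tibble(
      n = n, score_n = s_n, score_n1 = s_n1, magnitude = magnitude,
      reversed = rev$reversed, reversal_week = rev$reversal_week
    ))
  }
  dplyr::arrange(out, .data$n)
}

#' Detect sudden gains across a whole cohort
#'
#' Runs [detect_gains()] on every participant's weekly LSAS series and marks
#' each participant's primary gain (largest magnitude, ties to the earliest
#' week; see [select_primary_gain()]).
#'
#' @param cohort Validated long cohort tibble (typically the `included`
#'   element of [apply_inclusion_filter()]).
#' @param criteria A [gain_criteria()] object.
#' @return Tibble with columns `participant_id`, `n`, `score_n`, `score_n1`,
#'   `magnitude`, `reversed`, `reversal_week`, `is_primary`; zero rows if no
#'   gains anywhere.
#' @export
detect_sudden_gains <- function(cohort, criteria = gain_criteria()) {
  series <- cohort_lsas_series(cohort)
  gains <- purrr::imap(series, function(x, id) {
    g <- detect_gains(x, criteria)
    if (nrow(g)) dplyr::mutate(g, participant_id = id, .before = 1) else NULL
  })
  gains <- dplyr::bind_rows(gains)
  if (!nrow(gains)) {
    return(dplyr::mutate(
      tibble::tibble(participant_id = character(), !!!empty_gain_rows()),
      is_primary = logical()
    ))
  }
  gains |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(is_primary = mark_primary(.data$magnitude, .data$n)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$participant_id, .data$n)
}

#' Reversal check for one sudden gain
#'
#' A gain is reversed if the participant later loses at least half of it:
#' any subsequent observed LSAS value at or above
#' `score_n1 + 0.5 * magnitude` (inclusive) counts. For the classic worked
#' example of a 60 to 40 gain, a later score of 50 or more is a reversal.
#'
#' @param score_n1 Post-gain LSAS score (week `n + 1`).
#' @param magnitude Gain magnitude, `score_n - score_n1`.
#' @param subsequent_values LSAS values at weeks after `n + 1` (may contain
#'   `NA`; may be empty).
#' @param subsequent_weeks Week indices matching `subsequent_values`.
#' @return List with `reversed` (logical) and `reversal_week` (first week
#'   meeting the rule, `NA` if none).
#' @export
#' @examples
#' detect_reversal(40, 20, c(42, 50, 44), 6:8) # reversed at week 7
detect_reversal <- function(score_n1, magnitude, subsequent_values,
                            subsequent_weeks = seq_along(subsequent_values)) {
  stopifnot(length(subsequent_values) == length(subsequent_weeks))
  threshold <- score_n1 + 0.5 * magnitude
  hit <- which(!is.na(subsequent_values) & subsequent_values >= threshold)
  if (length(hit)) {
    list(reversed = TRUE, reversal_week = as.integer(subsequent_weeks[hit[1]]))
  } else {
    list(reversed = FALSE, reversal_week = NA_integer_)
  }
}

#' Select a participant's primary gain
#'
#' When a participant has several sudden gains, the one with the largest
#' magnitude is taken as the primary gain for group analyses (the more
#' clinically significant change); ties go to the earliest pre-gain week.
#'
#' @param gains Tibble of gains for ONE participant (rows of
#'   [detect_gains()] output).
#' @return A one-row tibble, or `NULL` when `gains` has no rows.
#' @export
select_primary_gain <- function(gains) {
  if (is.null(gains) || nrow(gains) == 0) return(NULL)
  gains[which(mark_primary(gains$magnitude, gains$n)), , drop = FALSE]
}

# logical vector with TRUE at the primary gain (max magnitude, earliest n)
mark_primary <- function(magnitude, n) {
  pick <- order(-magnitude, n)[1]
  seq_along(magnitude) == pick
}

# named list of weekly LSAS vectors (index = week), one per participant
cohort_lsas_series <- function(cohort) {
  lsas <- dplyr::filter(cohort, .data$measure == "lsas")
  if (!nrow(lsas)) return(list())
  split(lsas, lsas$participant_id) |>
    purrr::map(function(d) {
      x <- rep(NA_real_, max(d$week))
      x[d$week] <- d$value
      x
    })
}

as_lsas_vector <- function(lsas) {
  if (is.data.frame(lsas)) {
    stopifnot(all(c("week", "value") %in% names(lsas)))
    x <- rep(NA_real_, max(lsas$week))
    x[lsas$week] <- lsas$value
    return(x)
  }
  as.numeric(lsas)
}

empty_gain_rows <- function() {
  tibble::tibble(n = integer(), score_n = double(), score_n1 = double(),
                 magnitude = double(), reversed = logical(),
                 reversal_week = integer())
}
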