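#' Sudden-gain classification criteria
#'
#' Parameter set for the three-criterion sudden-gain definition on weekly
#' LSAS scores. A drop from week `n` (pre-gain) to week `n + 1` (post-gain)
#' is a sudden gain when all three hold:
#'
#' 1. **Absolute magnitude**: the drop is at least `cutoff` points
#'    (default 12, a reliable-change threshold for the LSAS).
#' 2. **Relative magnitude**: the drop is at least `pct` (default 25%) of
#'    the pre-gain score.
#' 3. **Stability**: the mean of the up-to-three pre-gain scores (weeks
#'    `n-2..n`) exceeds the mean of the up-to-three post-gain scores (weeks
#'    `n+1..n+3`) by more than a critical multiple of their pooled standard
#'    deviation. With full 3 + 3 windows the multiplier is the two-sided
#'    Student-t quantile 2.776 (commonly printed 2.78); when one value in a
#'    window is missing the multiplier grows (3.182, then 4.303 for 2 + 2),
#'    making the test more stringent. See [critical_value()].
#'
#' Criteria 1 and 2 are inclusive (a drop of exactly 12 points, or exactly
#' 25%, qualifies); criterion 3 is a strict inequality.
#'
#' @param cutoff Minimum absolute LSAS drop (points), > 0.
#' @param pct Minimum drop as a fraction of the pre-gain score, in (0, 1).
#' @param stability_alpha Two-sided tail probability behind the criterion-3
#'   critical value (default 0.05, giving 2.776 for full windows).
#' @param min_window Minimum non-missing values required in each of the pre
#'   and post windows (2 or 3). At 2, at most one value per window may be
#'   missing; at 3, complete windows are required.
#' @return A list of class `gain_criteria`.
#' @export
#' @examples
#' gain_criteria()
#' gain_criteria(min_window = 3) # complete windows only
gain_criteria <- function(cutoff = 12, pct = 0.25, stability_alpha = 0.05,
                          min_window = 2L) {
  stopifnot(cutoff > 0, pct > 0, pct < 1,
            stability_alpha > 0, stability_alpha < 1,
            min_window %in% c(2L, 3L))
  structure(
    list(cutoff = cutoff, pct = pct, stability_alpha = stability_alpha,
         min_window = as.integer(min_window)),
    class = "gain_criteria"
  )
}

#' @export
print.gain_criteria <- function(x, ...) {
  cat("Sudden-gain criteria:\n",
      "  1. absolute drop >= ", x$cutoff, " points\n",
      "  2. relative drop >= ", 100 * x$pct, "% of pre-gain score\n",
      "  3. mean(pre) - mean(post) > t(", x$stability_alpha,
      ", df = n_pre + n_post - 2) x pooled SD\n",
      "  windows: >= ", x$min_window, " observed values each\n", sep = "")
  invisible(x)
}

#' Criterion 1: absolute drop cutoff
#'
#' @param score_n LSAS at the pre-gain week `n` (non-missing).
#' @param score_n1 LSAS at the post-gain week `n + 1` (non-missing).
#' @param cutoff Minimum drop in points (default 12).
#' @return Logical: `score_n - score_n1 >= cutoff` (inclusive).
#' @export
#' @examples
#' check_criterion1(60, 40) # drop 20 -> TRUE
#' check_criterion1(60, 49) # drop 11 -> FALSE
check_criterion1 <- function(score_n, score_n1, cutoff = 12) {
  if (anyNA(c(score_n, score_n1))) {
    abort("criterion 1 requires non-missing scores at weeks n and n+1")
  }
  (score_n - score_n1) >= cutoff
}

#' Criterion 2: drop relative to the pre-gain score
#'
#' A zero pre-gain score admits no positive drop; it returns `FALSE` with a
#' message rather than erroring, so cohort scans keep going.
#'
#' @inheritParams check_criterion1
#' @param pct Minimum fractional drop (default 0.25).
#' @return Logical: `score_n - score_n1 >= pct * score_n` (inclusive).
#' @export
#' @examples
#' check_criterion2(60, 45) # 15 >= 15 -> TRUE ("at least 25%")
#' check_criterion2(100, 80) # 20 < 25 -> FALSE
check_criterion2 <- function(score_n, score_n1, pct = 0.25) {
  if (anyNA(c(score_n, score_n1))) {
    abort("criterion 2 requires non-missing scores at weeks n and n+1")
  }
  if (score_n <= 0) {
    inform("criterion 2: pre-gain score is 0; no positive drop possible")
    return(FALSE)
  }
  (score_n - score_n1) >= pct * score_n
}

#' Criterion-3 critical value with missing-data adjustment
#'
#' Two-sided Student-t quantile at `1 - stability_alpha / 2` with
#' `n_pre + n_post - 2` degrees of freedom. Full 3 + 3 windows give 2.776
#' (printed as 2.78 in the sudden-gains literature); removing one
#' observation gives 3.182 (2 + 3 or 3 + 2) and removing one from each
#' window gives 4.303 (2 + 2), so the stability test only ever becomes more
#' stringent as data go missing.
#'
#' @param n_pre,n_post Number of non-missing values in the pre and post
#'   windows; each must be 2 or 3.
#' @param stability_alpha Two-sided tail probability (default 0.05).
#' @return The critical multiplier (numeric scalar).
#' @export
#' @examples
#' critical_value(3, 3) # 2.776
#' critical_value(2, 3) # 3.182
#' critical_value(2, 2) # 4.303
critical_value <- function(n_pre, n_post, stability_alpha = 0.05) {
  if (!(n_pre %in% 2:3) || !(n_post %in% 2:3)) {
    abort("window sizes must be 2 or 3 observed values")
  }
  qt(1 - stability_alpha / 2, df = n_pre + n_post - 2)
}

#' Criterion 3: stability relative to symptom fluctuation
#'
#' Tests whether the gain stands out from week-to-week fluctuation:
#' `mean(pre) - mean(post)` must strictly exceed
#' `critical_value(n_pre, n_post) * pooled_sd`, where
#' `pooled_sd = sqrt((sd_pre^2 + sd_post^2) / 2)` with sample (n-1) SDs.
#' With zero variance in both windows any positive mean difference passes.
#'
#' @param pre Non-missing LSAS values from weeks `n-2..n` (length 2 or 3).
#' @param post Non-missing LSAS values from weeks `n+1..n+3` (length 2 or 3).
#' @param criteria A [gain_criteria()] object.
#' @return Logical.
#' @export
#' @examples
#' check_criterion3(c(60, 60, 60), c(40, 40, 40)) # TRUE (zero variance)
#' check_criterion3(c(60, 50, 60), c(40, 50, 40)) # FALSE (too much scatter)
check_criterion3 <- function(pre, post, criteria = gain_criteria()) {
  pre <- pre[!is.na(pre)]
  post <- post[!is.na(post)]
  if (length(pre) < criteria$min_window || length(post) < criteria$min_window) {
    abort("criterion 3 requires at least min_window observed values per window")
  }
  crit <- critical_value(length(pre), length(post), criteria$stability_alpha)
  psd <- pooled_window_sd(pre, post)
  (mean(pre) - mean(post)) > crit * psd
}

# sqrt of the mean of the two sample variances
pooled_window_sd <- function(pre, post) {
  sqrt((var(pre) + var(post)) / 2)
}
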