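#' Pooled sample standard deviation of two cells
#'
#' Classic (n-1)-weighted pooling:
#' `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param s1,s2 Sample SDs of the two cells.
#' @param n1,n2 Cell sizes (each >= 2).
#' @return Numeric scalar.
#' @export
pooled_sd <- function(s1, n1, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
}

#' Cohen's d for a model contrast
#'
#' Standardises a (possibly covariate-adjusted) contrast estimate by the
#' pooled raw-score standard deviation of the two compared cells:
#' `d = |estimate| / sd_raw`. Model-based contrast, raw-score denominator;
#' with zero dispersion the effect size is undefined and `NA` is returned
#' with a message.
#'
#' @param estimate Contrast estimate (difference of two cell means).
#' @param sd_raw Pooled raw sample SD of the measure across the two cells
#'   (see [pooled_sd()]).
#' @return Numeric scalar, `NA` if `sd_raw` is zero or missing.
#' @export
#' @examples
#' cohens_d(10, 10) # 1
cohens_d <- function(estimate, sd_raw) {
  if (is.na(sd_raw) || sd_raw <= 0) {
    inform("cohens_d: zero or missing dispersion; effect size undefined")
    return(NA_real_)
  }
  abs(estimate) / sd_raw
}
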