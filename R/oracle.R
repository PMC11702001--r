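#' Brute-force sudden-gain oracle
#'
#' An independent, deliberately plain re-implementation of the
#' three-criterion classification, used to certify synthetic trajectories
#' (see [simulate_cohort()]) and to cross-check [detect_gains()] in the test
#' suite. It walks every adjacent week pair from scratch, recomputing means
#' and variances by explicit sums, and shares no code with the detector
#' beyond base R.
#'
#' @param lsas Numeric vector of weekly LSAS values indexed by week; `NA` =
#'   missing.
#' @param cutoff,pct,stability_alpha,min_window Criteria parameters, as in
#'   [gain_criteria()].
#' @return Integer vector of qualifying pre-gain weeks `n` (possibly empty).
#' @export
oracle_detect <- function(lsas, cutoff = 12, pct = 0.25,
                          stability_alpha = 0.05, min_window = 2) {
  x <- as.numeric(lsas)
  W <- length(x)
  hits <- integer(0)
  if (W < 2) return(hits)
  for (i in 1:(W - 1)) {
    a <- x[i]
    b <- x[i + 1]
    if (is.na(a) || is.na(b)) next

    pre_weeks <- (i - 2):i
    pre_weeks <- pre_weeks[pre_weeks >= 1]
    post_weeks <- (i + 1):(i + 3)
    post_weeks <- post_weeks[post_weeks <= W]
    pv <- x[pre_weeks]
    pv <- pv[!is.na(pv)]
    qv <- x[post_weeks]
    qv <- qv[!is.na(qv)]
    if (length(pv) < min_window || length(qv) < min_window) next

    # criterion 1: absolute drop of at least `cutoff` points (inclusive)
    if (a - b < cutoff) next
    # criterion 2: drop of at least 100*pct percent of the pre-gain score
    if (a <= 0) next
    if ((a - b) / a < pct) next
    # criterion 3: mean difference strictly beyond t-critical x pooled SD
    mp <- sum(pv) / length(pv)
    mq <- sum(qv) / length(qv)
    vp <- sum((pv - mp)^2) / (length(pv) - 1)
    vq <- sum((qv - mq)^2) / (length(qv) - 1)
    psd <- sqrt((vp + vq) / 2)
    tcrit <- stats::qt(stability_alpha / 2,
                       df = length(pv) + length(qv) - 2,
                       lower.tail = FALSE)
    if (mp - mq <= tcrit * psd) next

    hits <- c(hits, i)
  }
  hits
}
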