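#' Process model: measure trajectories around the gain
#'
#' Fits a maximum-likelihood linear mixed-effects model of one process
#' measure on the six categorical timepoints around the primary sudden gain
#' (`n-2 .. n+3`), with a random intercept per participant:
#'
#' `value ~ timepoint + (1 | participant)`
#'
#' Missing rows are dropped (no imputation). Timepoint levels with no
#' observations are dropped from the factor before fitting.
#'
#' @param around_long Output of [extract_around_gain()] (or any tibble with
#'   `participant_id`, `measure`, `timepoint`, `value`).
#' @param measure Which measure to model.
#' @return Object of class `sg_process_fit`: list with `model` (`nlme::lme`),
#'   `measure`, `data` (the rows used), `cell_stats` (per-timepoint mean,
#'   SD, n of the raw values).
#' @export
fit_process_model <- function(around_long, measure) {
  d <- around_long |>
    dplyr::filter(.data$measure == !!measure, !is.na(.data$value)) |>
    dplyr::mutate(timepoint = droplevels(factor(.data$timepoint,
                                                levels = sg_timepoint_levels)))
  usable <- d |>
    dplyr::count(.data$timepoint) |>
    dplyr::filter(.data$n >= 2)
  if (nrow(usable) < 2) {
    abort(paste0("measure '", measure,
                 "' has fewer than 2 timepoints with at least 2 observations"))
  }

  # returnObject tolerates the boundary fit on degenerate (e.g. constant)
  # inputs, where estimates are exact but the optimizer reports non-progress
  model <- suppressWarnings(
    nlme::lme(value ~ timepoint, random = ~ 1 | participant_id,
              data = d, method = "ML", na.action = na.omit,
              control = nlme::lmeControl(returnObject = TRUE))
  )

  cell_stats <- d |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop")

  structure(list(model = model, measure = measure, data = d,
                 cell_stats = cell_stats),
            class = "sg_process_fit")
}

#' @export
print.sg_process_fit <- function(x, ...) {
  cat("Around-gain process model for '", x$measure, "' (LMM, ML)\n", sep = "")
  print(as.data.frame(x$cell_stats), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Consecutive timepoint contrasts with Bonferroni correction
#'
#' Estimates the five consecutive contrasts (`n-2 vs n-1`, ..., `n+2 vs
#' n+3`) from a fitted around-gain process model via estimated marginal
#' means. Each estimate is the later timepoint's marginal mean minus the
#' earlier one's, so improvement on a lower-is-better scale shows as a
#' negative estimate. Raw p-values (t tests with containment degrees of
#' freedom, a between-within approximation) are Bonferroni-adjusted within
#' the measure: `p_adj = min(1, k * p)` where `k` is the number of
#' contrasts (5 with complete timepoints). Cohen's d standardises each
#' contrast by the pooled raw-score SD of its two timepoint cells.
#'
#' @param fit An `sg_process_fit` from [fit_process_model()].
#' @param bonferroni_k Family size for the correction; defaults to the
#'   number of estimated contrasts.
#' @return Tibble: `measure`, `contrast` (e.g. `"n vs n+1"`), `estimate`,
#'   `se`, `df`, `p_value`, `p_adj`, `d`.
#' @export
consecutive_contrasts <- function(fit, bonferroni_k = NULL) {
  stopifnot(inherits(fit, "sg_process_fit"))
  emm <- emmeans::emmeans(fit$model, ~ timepoint, data = fit$data)
  ctr <- summary(emmeans::contrast(emm, method = "consec", adjust = "none"))
  lev <- levels(fit$data$timepoint)
  k <- bonferroni_k %||% nrow(ctr)

  cells <- fit$cell_stats
  purrr::map_dfr(seq_len(nrow(ctr)), function(i) {
    earlier <- lev[i]
    later <- lev[i + 1]
    c1 <- cells[cells$timepoint == earlier, ]
    c2 <- cells[cells$timepoint == later, ]
    d <- if (nrow(c1) == 1 && nrow(c2) == 1 && c1$n >= 2 && c2$n >= 2) {
      cohens_d(ctr$estimate[i], pooled_sd(c1$sd, c1$n, c2$sd, c2$n))
    } else NA_real_
    tibble::tibble(
      measure = fit$measure,
      contrast = paste(earlier, "vs", later),
      estimate = ctr$estimate[i],
      se = ctr$SE[i],
      df = ctr$df[i],
      p_value = ctr$p.value[i],
      p_adj = pmin(1, k * ctr$p.value[i]),
      d = d
    )
  })
}

#' @rdname consecutive_contrasts
#' @param x An `sg_process_fit`.
#' @param ... Unused.
#' @export
tidy.sg_process_fit <- function(x, ...) consecutive_contrasts(x, ...)

#' @export
glance.sg_process_fit <- function(x, ...) {
  tibble::tibble(
    measure = x$measure,
    n_participants = dplyr::n_distinct(x$data$participant_id),
    n_obs = nrow(x$data),
    sigma = x$model$sigma,
    logLik = as.numeric(logLik(x$model)),
    AIC = AIC(x$model)
  )
}

#' Contrast table across all process measures
#'
#' Convenience wrapper fitting [fit_process_model()] per measure and
#' stacking the [consecutive_contrasts()] rows into one table (the layout
#' used to report process changes around sudden gains). Measures that
#' cannot be fitted are skipped with a message.
#'
#' @inheritParams fit_process_model
#' @param measures Measures to model; defaults to all present.
#' @return Tibble as in [consecutive_contrasts()], stacked over measures.
#' @export
process_contrast_table <- function(around_long,
                                   measures = unique(around_long$measure)) {
  purrr::map_dfr(measures, function(m) {
    fit <- tryCatch(fit_process_model(around_long, m), error = function(e) {
      inform(paste0("skipping measure '", m, "': ", conditionMessage(e)))
      NULL
    })
    if (is.null(fit)) return(NULL)
    consecutive_contrasts(fit)
  })
}
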