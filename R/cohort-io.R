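#' Read a cohort of weekly measurement trajectories
#'
#' Reads weekly per-participant outcome data from CSV in either of two
#' layouts and returns a validated long tibble, one row per
#' (participant, week, measure):
#'
#' * **long**: columns `participant_id, week, measure, value` (empty string
#'   or `NA` = missing value).
#' * **wide**: a `participant_id` column plus one column per measure-week
#'   named `<measure>_w<k>`, e.g. `lsas_w1`, `scq_freq_w12`.
#'
#' Validation enforces: weeks are strictly positive integers, measure names
#' appear in the registry, non-missing values lie within the registered
#' scale range, and no (participant, week, measure) cell is duplicated.
#' Out-of-range values raise an error naming the offending rows; nothing is
#' silently clamped.
#'
#' @param path CSV file path.
#' @param format `"long"` or `"wide"`.
#' @param registry Measure registry tibble; defaults to [sg_measures()].
#' @return A tibble with columns `participant_id` (character), `week`
#'   (integer), `measure` (character), `value` (double, `NA` = missing),
#'   sorted by participant, measure, week.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path, format = c("long", "wide"), registry = sg_measures()) {
  format <- match.arg(format)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "#")
  cohort <- if (format == "long") {
    need <- c("participant_id", "week", "measure", "value")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols)) {
      abort(paste0("long cohort CSV is missing column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    dplyr::transmute(raw,
      participant_id = as.character(.data$participant_id),
      week = .data$week,
      measure = as.character(.data$measure),
      value = as.numeric(.data$value)
    )
  } else {
    if (!"participant_id" %in% names(raw)) {
      abort("wide cohort CSV must have a participant_id column")
    }
    valcols <- setdiff(names(raw), "participant_id")
    bad <- valcols[!grepl("^.+_w[0-9]+$", valcols)]
    if (length(bad)) {
      abort(paste0("wide columns must be named <measure>_w<k>; offending: ",
                   paste(bad, collapse = ", ")))
    }
    raw |>
      dplyr::mutate(participant_id = as.character(.data$participant_id)) |>
      tidyr::pivot_longer(-"participant_id",
                          names_to = c("measure", "week"),
                          names_pattern = "^(.*)_w([0-9]+)$",
                          values_to = "value") |>
      dplyr::mutate(week = as.numeric(.data$week),
                    value = as.numeric(.data$value))
  }
  validate_cohort(cohort, registry)
}

#' Validate a long cohort tibble against a measure registry
#'
#' @param cohort Long tibble with `participant_id`, `week`, `measure`, `value`.
#' @param registry Measure registry tibble (see [sg_measures()]).
#' @return The cohort, with `week` coerced to integer, sorted.
#' @export
validate_cohort <- function(cohort, registry = sg_measures()) {
  validate_registry(registry)
  cohort <- tibble::as_tibble(cohort)

  if (any(is.na(cohort$week)) || any(cohort$week < 1) ||
      any(cohort$week != as.integer(cohort$week))) {
    abort("weeks must be strictly positive integers")
  }
  cohort$week <- as.integer(cohort$week)

  unknown <- setdiff(unique(cohort$measure), registry$measure)
  if (length(unknown)) {
    abort(paste0("unknown measure name(s): ", paste(unknown, collapse = ", ")))
  }

  dup <- duplicated(cohort[, c("participant_id", "week", "measure")])
  if (any(dup)) {
    d <- cohort[dup, ]
    abort(paste0(
      "duplicate (participant, week, measure) cell(s), e.g. ",
      d$participant_id[1], " / week ", d$week[1], " / ", d$measure[1]
    ))
  }

  joined <- dplyr::left_join(cohort, registry, by = "measure")
  oob <- !is.na(joined$value) &
    (joined$value < joined$min_value | joined$value > joined$max_value)
  if (any(oob)) {
    o <- joined[oob, ]
    abort(paste0(
      sum(oob), " value(s) outside the registered scale range; first: ",
      o$measure[1], " = ", o$value[1], " (allowed ", o$min_value[1], "-",
      o$max_value[1], ") for participant ", o$participant_id[1],
      " week ", o$week[1]
    ))
  }

  cohort |>
    dplyr::relocate("participant_id", "week", "measure", "value") |>
    dplyr::arrange(.data$participant_id, .data$measure, .data$week)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]; a round trip through `write_cohort()` and
#' `read_cohort()` preserves every (participant, week, measure, value) cell.
#'
#' @inheritParams read_cohort
#' @param cohort Validated long cohort tibble.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("long", "wide")) {
  format <- match.arg(format)
  out <- if (format == "long") {
    dplyr::arrange(cohort, .data$participant_id, .data$measure, .data$week)
  } else {
    cohort |>
      dplyr::mutate(col = paste0(.data$measure, "_w", .data$week)) |>
      dplyr::select("participant_id", "col", "value") |>
      tidyr::pivot_wider(names_from = "col", values_from = "value")
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read post-intervention / follow-up endpoint scores
#'
#' @param path CSV with columns `participant_id,lsas_post,lsas_fu3m`
#'   (either endpoint may be empty = missing).
#' @return Tibble with those three columns.
#' @export
read_endpoints <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "#")
  need <- c("participant_id", "lsas_post", "lsas_fu3m")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(paste0("endpoints CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dplyr::transmute(raw,
    participant_id = as.character(.data$participant_id),
    lsas_post = as.numeric(.data$lsas_post),
    lsas_fu3m = as.numeric(.data$lsas_fu3m)
  )
}

#' Per-participant metadata for a cohort
#'
#' @param cohort Validated long cohort tibble.
#' @return Tibble with `participant_id`, `n_weeks` (largest week index
#'   present), `n_lsas_points` (count of non-missing weekly LSAS values),
#'   and `baseline_lsas` (LSAS at week 1, `NA` if unobserved).
#' @export
cohort_metadata <- function(cohort) {
  cohort |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_weeks = max(.data$week),
      n_lsas_points = sum(.data$measure == "lsas" & !is.na(.data$value)),
      baseline_lsas = {
        b <- .data$value[.data$measure == "lsas" & .data$week == 1L]
        if (length(b)) b[1] else NA_real_
      },
      .groups = "drop"
    )
}
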