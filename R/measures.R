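#' Default weekly measure registry
#'
#' The measures tracked weekly during internet-delivered cognitive therapy
#' for social anxiety disorder, with their scale ranges:
#'
#' * `lsas` — 24-item Liebowitz Social Anxiety Scale total (0–144); the
#'   detection measure. Lower is better.
#' * `scq_freq` — Social Cognitions Questionnaire frequency, 22 items each
#'   rated 1–5, stored as the summed scale (22–110).
#' * `scq_belief` — SCQ belief ratings, 22 items each 0–100, summed (0–2200).
#' * `sfa_general`, `sfa_difficult` — self-focused attention in general and
#'   in difficult social situations, single items from the Social Phobia
#'   Weekly Summary Scale (0–8).
#' * `phq9` — 9-item depression measure (0–27).
#'
#' All measures are scored so that lower values indicate improvement.
#'
#' @return A tibble with columns `measure`, `min_value`, `max_value`,
#'   `lower_is_better`.
#' @export
#' @examples
#' sg_measures()
sg_measures <- function() {
  tibble::tribble(
    ~measure,        ~min_value, ~max_value, ~lower_is_better,
    "lsas",                   0,        144,             TRUE,
    "scq_freq",              22,        110,             TRUE,
    "scq_belief",             0,       2200,             TRUE,
    "sfa_general",            0,          8,             TRUE,
    "sfa_difficult",          0,          8,             TRUE,
    "phq9",                   0,         27,             TRUE
  )
}

#' Read a measure registry from a JSON or YAML config file
#'
#' The file must contain a list of entries with fields `measure`,
#' `min_value`, `max_value` and optionally `lower_is_better` (default TRUE).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated registry tibble (see [sg_measures()]).
#' @export
read_measure_registry <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    yaml = ,
    yml = {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        abort("reading YAML registries requires the 'yaml' package")
      }
      do.call(rbind, lapply(yaml::read_yaml(path), as.data.frame))
    },
    abort(paste0("unsupported registry format: '", ext, "'"))
  )
  reg <- tibble::as_tibble(raw)
  if (!all(c("measure", "min_value", "max_value") %in% names(reg))) {
    abort("registry must provide fields: measure, min_value, max_value")
  }
  if (!"lower_is_better" %in% names(reg)) reg$lower_is_better <- TRUE
  validate_registry(reg[, c("measure", "min_value", "max_value", "lower_is_better")])
}

validate_registry <- function(registry) {
  if (anyDuplicated(registry$measure)) {
    abort("measure names in the registry must be unique")
  }
  bad <- registry$min_value >= registry$max_value
  if (any(bad)) {
    abort(paste0(
      "min_value must be below max_value; offending measure(s): ",
      paste(registry$measure[bad], collapse = ", ")
    ))
  }
  registry
}
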