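two_measure_cohort <- function() {
  dplyr::bind_rows(
    lsas_traj("p1", c(85, 84, 83, 82, 81, 55, 54, 53, 52, 51, 50, 49, 48, 47)),
    tibble::tibble(participant_id = "p1", week = 1:14, measure = "phq9",
                   value = c(12, 12, 11, 11, 11, 8, 8, 8, 7, 7, 7, 6, 6, 6))
  )
}

test_that("six offsets are extracted at absolute weeks with LSAS included", {
  cohort <- two_measure_cohort()
  primary <- tibble::tibble(participant_id = "p1", n = 5)
  out <- extract_around_gain(cohort, primary)
  expect_equal(nrow(out), 12)  # 2 measures x 6 timepoints
  lsas <- dplyr::filter(out, measure == "lsas")
  expect_equal(lsas$week, 3:8)
  expect_equal(lsas$value, c(83, 82, 81, 55, 54, 53))
  expect_equal(as.character(lsas$timepoint),
               c("n-2", "n-1", "n", "n+1", "n+2", "n+3"))
})

test_that("offsets beyond the trajectory edges are missing by construction", {
  cohort <- two_measure_cohort()
  out <- extract_around_gain(cohort, tibble::tibble(participant_id = "p1", n = 2),
                             measures = "lsas")
  expect_true(is.na(out$value[out$timepoint == "n-2"]))  # week 0
  out2 <- extract_around_gain(cohort,
                              tibble::tibble(participant_id = "p1", n = 13),
                              measures = "lsas")
  expect_true(all(is.na(out2$value[out2$timepoint %in% c("n+2", "n+3")])))
})

test_that("a missing week stays missing (no nearest-observation substitution)", {
  cohort <- lsas_traj("p1", c(85, 84, NA, 82, 81, 55, 54, 53, 52))
  out <- extract_around_gain(cohort, tibble::tibble(participant_id = "p1", n = 5),
                             measures = "lsas")
  expect_true(is.na(out$value[out$timepoint == "n-2"]))  # week 3 was missing
  expect_equal(out$value[out$timepoint == "n-1"], 82)
})

test_that("extraction is invariant to input row order and checks membership", {
  cohort <- two_measure_cohort()
  primary <- tibble::tibble(participant_id = "p1", n = 5)
  shuffled <- cohort[sample(nrow(cohort)), ]
  expect_equal(extract_around_gain(shuffled, primary),
               extract_around_gain(cohort, primary))
  expect_error(
    extract_around_gain(cohort, tibble::tibble(participant_id = "ghost", n = 5)),
    "absent from cohort"
  )
  expect_error(
    extract_around_gain(cohort, tibble::tibble(participant_id = c("p1", "p1"),
                                               n = c(5, 7))),
    "one row per participant"
  )
})

test_that("extracted values equal the generator's ground truth", {
  cfg <- quiet_config(n_participants = 12, gain_prevalence = 1,
                      p_second_gain = 0, seed = 91)
  sim <- simulate_cohort(cfg)
  gains <- detect_sudden_gains(sim$cohort)
  primary <- dplyr::filter(gains, is_primary)
  out <- extract_around_gain(sim$cohort, primary, measures = "lsas")
  truth_weeks <- setNames(sim$truth$week, sim$truth$participant_id)
  for (id in primary$participant_id) {
    expect_equal(primary$n[primary$participant_id == id],
                 unname(truth_weeks[id]))
    got <- dplyr::filter(out, participant_id == id)
    src <- dplyr::filter(sim$cohort, participant_id == id, measure == "lsas")
    for (j in seq_len(nrow(got))) {
      if (is.na(got$week[j])) next
      expect_equal(got$value[j], src$value[src$week == got$week[j]])
    }
  }
})
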