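test_that("long CSV reading conserves rows and validates values", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::bind_rows(lsas_traj("a", c(80, 75, 70)),
                                    lsas_traj("b", c(90, NA, 85))), path)
  cohort <- read_cohort(path, "long")
  expect_equal(nrow(cohort), 6)
  expect_identical(sort(unique(cohort$participant_id)), c("a", "b"))
  expect_true(is.na(cohort$value[cohort$participant_id == "b" &
                                   cohort$week == 2]))
})

test_that("out-of-range, duplicate, and unknown-measure inputs error", {
  expect_error(validate_cohort(lsas_traj("a", c(80, 150, 70))),
               "outside the registered scale range")
  dup <- dplyr::bind_rows(lsas_traj("a", c(80, 75)), lsas_traj("a", 80))
  expect_error(validate_cohort(dup), "duplicate")
  bad <- tibble::tibble(participant_id = "a", week = 1,
                        measure = "nonsense", value = 3)
  expect_error(validate_cohort(bad), "unknown measure")
  expect_error(validate_cohort(tibble::tibble(participant_id = "a", week = 0,
                                              measure = "lsas", value = 3)),
               "strictly positive")
})

test_that("writer/reader round trip is exact in both formats", {
  cohort <- validate_cohort(dplyr::bind_rows(
    lsas_traj("a", c(80, 75, NA, 64)),
    lsas_traj("b", c(90, 85, 81, 70)),
    tibble::tibble(participant_id = "a", week = 1:4, measure = "phq9",
                   value = c(12, NA, 10, 9)),
    tibble::tibble(participant_id = "b", week = 1:4, measure = "phq9",
                   value = c(15, 14, NA, 11))
  ))
  for (fmt in c("long", "wide")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_cohort(cohort, path, fmt)
    back <- read_cohort(path, fmt)
    expect_equal(
      dplyr::arrange(back, participant_id, measure, week),
      dplyr::arrange(cohort, participant_id, measure, week)
    )
  }
})

test_that("measure registry files load and are checked", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(sg_measures(), path)
  expect_equal(read_measure_registry(path), sg_measures())
  bad <- sg_measures()
  bad$min_value[1] <- 200
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, path2)
  expect_error(read_measure_registry(path2), "min_value")
})

test_that("inclusion filter applies the 8-datapoint boundary to observed LSAS", {
  cohort <- dplyr::bind_rows(
    lsas_traj("exactly8", 80:73),                       # 8 observed -> in
    lsas_traj("only7", c(80:74, NA)),                   # 7 observed -> out
    lsas_traj("long_sparse", c(80, NA, 78, NA, 76, NA, 74, NA, 72,
                               NA, NA, NA, NA, NA))     # 14 weeks, 5 pts -> out
  )
  filt <- apply_inclusion_filter(cohort, min_lsas_points = 8)
  expect_identical(unique(filt$included$participant_id), "exactly8")
  expect_setequal(unique(filt$excluded$participant_id),
                  c("only7", "long_sparse"))
  expect_equal(filt$report$n_included, 1)
  expect_equal(filt$report$n_excluded, 2)
})

test_that("inclusion filter partitions any cohort and is idempotent", {
  set.seed(42)
  cohort <- purrr::map_dfr(1:12, function(i) {
    v <- rnorm(sample(8:14, 1), 80, 10)
    v[runif(length(v)) < 0.4] <- NA
    lsas_traj(paste0("p", i), round(v))
  })
  filt <- apply_inclusion_filter(cohort)
  n_ids <- function(d) dplyr::n_distinct(d$participant_id)
  expect_equal(n_ids(filt$included) + n_ids(filt$excluded), n_ids(cohort))
  expect_equal(nrow(filt$included) + nrow(filt$excluded), nrow(cohort))
  again <- apply_inclusion_filter(filt$included)
  expect_equal(again$included, filt$included)
  expect_equal(nrow(again$excluded), 0)
  empty <- apply_inclusion_filter(cohort[0, ])
  expect_equal(empty$report$n_total, 0)
})
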