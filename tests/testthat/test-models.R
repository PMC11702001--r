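noiseless_endpoints <- function(n = 40, diff = 10) {
  sg <- rep(c(TRUE, FALSE), length.out = n)
  tibble::tibble(
    participant_id = sprintf("p%02d", 1:n),
    sg = sg,
    # baseline varies but the outcome ignores it, so recovery stays exact
    baseline_lsas = seq(70, 95, length.out = n),
    lsas_post = 50 - diff * sg,
    lsas_fu3m = 45 - diff * sg
  )
}

test_that("outcome model recovers a noiseless group difference exactly", {
  fit <- fit_outcome_model(noiseless_endpoints(diff = 10))
  expect_equal(tidy(fit)$estimate, c(10, 10), tolerance = 1e-6)
  expect_equal(glance(fit)$n_participants, 40)
})

test_that("outcome model requires both gain groups", {
  ep <- noiseless_endpoints()
  ep$sg <- TRUE
  expect_error(fit_outcome_model(ep), "one sudden-gain group")
})

test_that("outcome model uses observed cell stats for Cohen's d", {
  set.seed(5)
  ep <- simulate_endpoints(n = 200, diff_post = 20, diff_fu = 15)
  fit <- fit_outcome_model(ep)
  td <- tidy(fit)
  cs <- dplyr::filter(fit$cell_stats, time == "post")
  d_hand <- abs(td$estimate[td$time == "post"]) /
    pooled_sd(cs$sd[1], cs$n[1], cs$sd[2], cs$n[2])
  expect_equal(td$d[td$time == "post"], d_hand)
  expect_true(all(td$se > 0))
  expect_true(all(td$p_value >= 0 & td$p_value <= 1))
})

test_that("pooled SD and Cohen's d match hand calculation on printed cells", {
  # two cells: 20.00 (SD 13.24, n 57) and 48.75 (SD 26.06, n 89)
  sp <- sqrt((56 * 13.24^2 + 88 * 26.06^2) / 144)
  expect_equal(pooled_sd(13.24, 57, 26.06, 89), sp)
  expect_equal(cohens_d(48.75 - 20.00, sp), 1.30791, tolerance = 1e-4)
  expect_equal(cohens_d(10, 10), 1)
  expect_equal(cohens_d(0, 10), 0)
  expect_message(expect_true(is.na(cohens_d(5, 0))), "dispersion")
})

flat_panel <- function(n = 12, value = 50) {
  tidyr::expand_grid(
    participant_id = sprintf("p%02d", 1:n),
    timepoint = factor(c("n-2", "n-1", "n", "n+1", "n+2", "n+3"),
                       levels = c("n-2", "n-1", "n", "n+1", "n+2", "n+3"))
  ) |>
    dplyr::mutate(measure = "phq9", week = NA_integer_, value = value)
}

test_that("identical values give zero timepoint effects and zero contrasts", {
  fit <- fit_process_model(flat_panel(value = 12), "phq9")
  ctr <- consecutive_contrasts(fit)
  expect_equal(ctr$estimate, rep(0, 5), tolerance = 1e-8)
  expect_equal(nrow(ctr), 5)
})

test_that("process model errors on unusable measures and names them", {
  panel <- flat_panel()
  panel$value[panel$timepoint != "n"] <- NA
  expect_error(fit_process_model(panel, "phq9"), "phq9")
})

test_that("contrast estimates telescope for balanced complete data", {
  set.seed(11)
  panel <- simulate_around_gain(30, "scq_freq", quiet_config())
  fit <- fit_process_model(panel, "scq_freq")
  ctr <- consecutive_contrasts(fit)
  cells <- fit$cell_stats
  span <- cells$mean[cells$timepoint == "n+3"] -
    cells$mean[cells$timepoint == "n-2"]
  expect_equal(sum(ctr$estimate), span, tolerance = 1e-6)
})

test_that("Bonferroni adjustment multiplies by the family size and caps at 1", {
  set.seed(12)
  panel <- simulate_around_gain(40, "scq_freq", quiet_config())
  ctr <- consecutive_contrasts(fit_process_model(panel, "scq_freq"))
  expect_equal(ctr$p_adj, pmin(1, 5 * ctr$p_value))
  expect_true(all(ctr$p_adj >= ctr$p_value))
  expect_true(all(ctr$p_adj <= 1))
  # a clearly null contrast lands at the 1.000 cap
  expect_true(any(ctr$p_adj == 1))
})

test_that("process estimates are invariant to participant order", {
  set.seed(13)
  panel <- simulate_around_gain(25, "sfa_general", quiet_config())
  shuffled <- panel[sample(nrow(panel)), ]
  c1 <- consecutive_contrasts(fit_process_model(panel, "sfa_general"))
  c2 <- consecutive_contrasts(fit_process_model(shuffled, "sfa_general"))
  expect_equal(c1$estimate, c2$estimate, tolerance = 1e-8)
  expect_equal(c1$p_value, c2$p_value, tolerance = 1e-8)
})

test_that("a drop injected only at the gain is recovered there and nowhere else", {
  set.seed(14)
  panel <- simulate_around_gain(80, "sfa_general", quiet_config())
  ctr <- consecutive_contrasts(fit_process_model(panel, "sfa_general"))
  at_gain <- ctr$contrast == "n vs n+1"
  expect_lt(ctr$p_adj[at_gain], 0.05)
  expect_equal(ctr$estimate[at_gain], -0.83, tolerance = 0.3)
  expect_true(all(abs(ctr$estimate[!at_gain]) < 0.4))
})

test_that("the contrast table stacks measures and skips unusable ones", {
  set.seed(15)
  panel <- dplyr::bind_rows(
    simulate_around_gain(20, "scq_freq", quiet_config()),
    simulate_around_gain(20, "phq9", quiet_config())
  )
  tbl <- process_contrast_table(panel)
  expect_setequal(unique(tbl$measure), c("scq_freq", "phq9"))
  expect_equal(nrow(tbl), 10)
  broken <- dplyr::mutate(panel, value = ifelse(measure == "phq9" &
                                                  timepoint != "n", NA, value))
  expect_message(tbl2 <- process_contrast_table(broken), "skipping")
  expect_setequal(unique(tbl2$measure), "scq_freq")
})
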