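test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(gain_prevalence = 1.5), "probabilities")
  expect_error(sim_config(duration_range = c(5, 30)), "duration_range")
  expect_error(sim_config(innovation_sd = -1), "positive")
  expect_error(sim_config(ar_coef = 1.2), "ar_coef")
})

test_that("equal seeds give bit-identical cohorts (and CSV bytes)", {
  cfg <- quiet_config(n_participants = 10, seed = 1)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth, b$truth)
  pa <- withr::local_tempfile(fileext = ".csv")
  pb <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a$cohort, pa)
  write_cohort(b$cohort, pb)
  expect_identical(readLines(pa), readLines(pb))
})

test_that("zero prevalence yields a cohort the oracle certifies gain-free", {
  cfg <- quiet_config(n_participants = 15, gain_prevalence = 0, seed = 2)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$truth), 0)
  series <- split(dplyr::filter(sim$cohort, measure == "lsas"),
                  dplyr::filter(sim$cohort, measure == "lsas")$participant_id)
  for (d in series) {
    x <- rep(NA_real_, max(d$week)); x[d$week] <- d$value
    expect_length(oracle_detect(x), 0)
  }
  expect_equal(nrow(detect_sudden_gains(sim$cohort)), 0)
})

test_that("full prevalence gives 100% participant-level sensitivity", {
  cfg <- quiet_config(n_participants = 40, gain_prevalence = 1,
                      p_second_gain = 0.25, seed = 3)
  sim <- simulate_cohort(cfg)
  gains <- detect_sudden_gains(sim$cohort)
  got <- dplyr::arrange(gains[, c("participant_id", "n")], participant_id, n)
  want <- dplyr::arrange(
    dplyr::transmute(sim$truth, participant_id, n = as.integer(week)),
    participant_id, n
  )
  expect_equal(got, want)
})

test_that("a near-noiseless flat no-gain trajectory is constant and gain-free", {
  cfg <- sim_config(innovation_sd = 1e-4, ar_coef = 0, missing_rate = 0,
                    slope_mean = 0, slope_sd = 1e-9)
  set.seed(4)
  s <- simulate_trajectory(cfg, "no_gain")
  lsas <- s$trajectory$value[s$trajectory$measure == "lsas"]
  expect_lt(diff(range(lsas)), 0.01)
  expect_equal(nrow(detect_gains(lsas)), 0)
})

test_that("a near-noiseless injected gain is detected exactly as injected", {
  cfg <- sim_config(innovation_sd = 1e-4, ar_coef = 0, missing_rate = 0,
                    slope_mean = 0, slope_sd = 1e-9)
  set.seed(5)
  s <- simulate_trajectory(cfg, "gain")
  lsas <- s$trajectory$value[s$trajectory$measure == "lsas"]
  g <- detect_gains(lsas)
  expect_equal(nrow(g), 1)
  expect_equal(g$n, as.integer(s$truth$week))
  expect_equal(g$magnitude, s$truth$magnitude, tolerance = 1e-2)
})

test_that("injected magnitudes are calibrated to the target mean", {
  cfg <- quiet_config()
  set.seed(6)
  mags <- unlist(replicate(400, simulate_trajectory(cfg, "gain")$truth$magnitude))
  mc_se <- sd(mags) / sqrt(length(mags))
  expect_lt(abs(mean(mags) - 25.29), 3 * mc_se + 0.3)
})

test_that("pre-gain weeks concentrate where the weights put them", {
  cfg <- quiet_config()
  set.seed(7)
  weeks <- unlist(replicate(300, simulate_trajectory(cfg, "gain")$truth$week))
  tab <- table(factor(weeks, levels = 2:12))
  expect_gte(min(weeks), 2)
  # weeks 2 and 6 are the modal choices by construction
  expect_true(all(tab[c("2", "6")] >= max(tab[c("4", "9", "11")])))
})

test_that("generated values respect every registered scale range", {
  cfg <- quiet_config(n_participants = 20, seed = 8)
  sim <- simulate_cohort(cfg)
  joined <- dplyr::left_join(sim$cohort, sg_measures(), by = "measure")
  ok <- is.na(joined$value) |
    (joined$value >= joined$min_value & joined$value <= joined$max_value)
  expect_true(all(ok))
  expect_setequal(unique(sim$cohort$measure), sg_measures()$measure)
})

test_that("AR(1) noise has the configured lag-1 autocorrelation", {
  set.seed(9)
  e <- suddenstep:::ar1_noise(20000, ar = 0.3, innovation_sd = 3)
  expect_equal(unname(acf(e, lag.max = 1, plot = FALSE)$acf[2]), 0.3,
               tolerance = 0.03)
})

test_that("missingness spares week 1 and the gain interval", {
  cfg <- quiet_config(missing_rate = 0.3)
  set.seed(10)
  for (i in 1:20) {
    s <- simulate_trajectory(cfg, "gain")
    lsas <- s$trajectory$value[s$trajectory$measure == "lsas"]
    expect_false(is.na(lsas[1]))
    expect_false(anyNA(lsas[c(s$truth$week, s$truth$week + 1)]))
  }
})

test_that("reversal scenarios can be switched on", {
  cfg <- quiet_config(reversal_rate = 1, duration_mean = 20)
  set.seed(11)
  revs <- replicate(25, {
    s <- simulate_trajectory(cfg, "gain")
    g <- detect_gains(s$trajectory$value[s$trajectory$measure == "lsas"])
    any(g$reversed)
  })
  expect_gt(mean(revs), 0.5)
})

test_that("certification failure reports the offending parameters", {
  # a 13-14 point gain on a ~135-point baseline can never satisfy the 25%
  # relative-drop criterion, so certification must give up and say so
  cfg <- quiet_config(innovation_sd = 0.5, ar_coef = 0,
                      baseline_mean_gain = 135, baseline_sd_gain = 0.001,
                      magnitude_mean = 13.5, magnitude_sd = 1,
                      magnitude_range = c(13, 14), max_attempts = 20)
  set.seed(12)
  expect_error(simulate_trajectory(cfg, "gain"), "certify")
})

test_that("the replication fixture has the designed gain structure", {
  fx <- make_replication_fixture()
  expect_equal(dplyr::n_distinct(fx$cohort$participant_id), 146)
  per <- dplyr::count(fx$truth, participant_id)
  expect_equal(sum(per$n == 1), 44)
  expect_equal(sum(per$n == 2), 13)
  expect_equal(nrow(fx$truth), 70)
  # regeneration with the documented seed is byte-identical
  expect_identical(fx$cohort, make_replication_fixture()$cohort)
})
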