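#' Default process-measure coupling parameters
#'
#' Per-measure generation parameters for the weekly process series and the
#' around-gain panel: a participant-level intercept (`level_mean`,
#' `level_sd`), a gentle weekly improvement `slope`, observation noise
#' `noise_sd`, and two coupled drops tied to the primary sudden gain:
#' `drop_pre` takes effect at the pre-gain week `n` (the interval before the
#' gain) and `drop_at` at week `n + 1` (simultaneous with the gain). Both
#' are persistent level shifts.
#'
#' Defaults encode the qualitative pattern reported around sudden gains in
#' internet cognitive therapy for social anxiety: negative-cognition
#' frequency (SCQ) starts falling one interval before the gain (standardised
#' drops of about 0.70 then 1.05), cognition belief and both self-focused
#' attention items drop simultaneously with the gain, and depressed mood
#' (PHQ-9) shows no coupled change.
#'
#' @return Tibble with columns `measure`, `level_mean`, `level_sd`, `slope`,
#'   `noise_sd`, `drop_pre`, `drop_at`.
#' @export
sg_process_params <- function() {
  tibble::tribble(
    ~measure,        ~level_mean, ~level_sd, ~slope, ~noise_sd, ~drop_pre, ~drop_at,
    "scq_freq",               72,         6,   0.60,       5.0,      5.50,     8.20,
    "scq_belief",           1150,       280,  12.00,     160.0,      0.00,   194.65,
    "sfa_general",           5.5,       1.2,   0.05,       0.7,      0.00,     0.83,
    "sfa_difficult",         6.0,       1.2,   0.05,       0.7,      0.00,     0.86,
    "phq9",                 12.0,       5.0,   0.08,       1.8,      0.00,     0.00
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic weekly-trajectory generator, calibrated to
#' the cohort the analysis targets: 8-30 week LSAS trajectories averaging
#' 14.5 weeks, baseline LSAS near 80-86 with SD near 19-21 (slightly higher
#' among eventual gainers), injected sudden gains of magnitude
#' N(25.29, 11.27) preferentially at pre-gain weeks 2 and 6, a
#' participant-level gain prevalence of 39% with 13/57 of gainers having a
#' second gain, AR(1)-correlated measurement noise, and
#' completely-at-random missingness.
#'
#' @param n_participants Cohort size.
#' @param gain_prevalence Probability a participant receives at least one
#'   injected gain.
#' @param p_second_gain Probability a gainer receives a second gain.
#' @param baseline_mean_gain,baseline_sd_gain Baseline LSAS distribution for
#'   gainers.
#' @param baseline_mean_nogain,baseline_sd_nogain Same for non-gainers.
#' @param magnitude_mean,magnitude_sd Injected gain magnitude distribution
#'   (LSAS points).
#' @param magnitude_range Truncation bounds for drawn magnitudes; the lower
#'   bound sits just above the 12-point cutoff so injected gains are
#'   detectable in principle.
#' @param pregain_week_weights Named numeric vector of sampling weights over
#'   candidate pre-gain weeks (bimodal by default, peaking at weeks 2 and
#'   6). Renormalised over the weeks feasible for a given duration.
#' @param duration_mean,duration_sd,duration_range Weeks-in-treatment
#'   distribution (rounded normal, clamped to the range).
#' @param slope_mean,slope_sd Gradual weekly LSAS improvement (points/week).
#' @param ar_coef,innovation_sd AR(1) measurement-noise process for LSAS.
#' @param missing_rate Completely-at-random weekly missingness probability;
#'   never applied at week 1 or at an injected gain's weeks `n`, `n + 1`.
#' @param reversal_rate Probability that an injected gain later rebounds
#'   above the 50%-loss threshold (default 0: reversals are rare in
#'   practice and opt-in here).
#' @param process Process-measure parameters; see [sg_process_params()].
#' @param min_lsas_points Certification floor on observed LSAS values so
#'   every simulated participant passes the inclusion filter.
#' @param max_attempts Resampling budget per participant for certification.
#' @param seed Optional integer seed; [simulate_cohort()] sets it before
#'   drawing anything, so equal seeds give bit-identical cohorts.
#' @return A list of class `sg_sim_config`.
#' @export
sim_config <- function(n_participants = 146,
                       gain_prevalence = 0.39,
                       p_second_gain = 13 / 57,
                       baseline_mean_gain = 85.74, baseline_sd_gain = 21.35,
                       baseline_mean_nogain = 80.12, baseline_sd_nogain = 18.88,
                       magnitude_mean = 25.29, magnitude_sd = 11.27,
                       magnitude_range = c(13, 60),
                       pregain_week_weights = c(
                         `2` = 0.20, `3` = 0.08, `4` = 0.08, `5` = 0.10,
                         `6` = 0.18, `7` = 0.09, `8` = 0.08, `9` = 0.07,
                         `10` = 0.08, `11` = 0.07, `12` = 0.05
                       ),
                       duration_mean = 14.53, duration_sd = 3.33,
                       duration_range = c(8, 30),
                       slope_mean = 2.2, slope_sd = 0.6,
                       ar_coef = 0.3, innovation_sd = 3,
                       missing_rate = 0.10,
                       reversal_rate = 0,
                       process = sg_process_params(),
                       min_lsas_points = 8,
                       max_attempts = 200,
                       seed = NULL) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    gain_prevalence = gain_prevalence,
    p_second_gain = p_second_gain,
    baseline_mean_gain = baseline_mean_gain,
    baseline_sd_gain = baseline_sd_gain,
    baseline_mean_nogain = baseline_mean_nogain,
    baseline_sd_nogain = baseline_sd_nogain,
    magnitude_mean = magnitude_mean, magnitude_sd = magnitude_sd,
    magnitude_range = magnitude_range,
    pregain_week_weights = pregain_week_weights,
    duration_mean = duration_mean, duration_sd = duration_sd,
    duration_range = as.integer(duration_range),
    slope_mean = slope_mean, slope_sd = slope_sd,
    ar_coef = ar_coef, innovation_sd = innovation_sd,
    missing_rate = missing_rate,
    reversal_rate = reversal_rate,
    process = process,
    min_lsas_points = as.integer(min_lsas_points),
    max_attempts = as.integer(max_attempts),
    seed = seed
  )
  validate_sim_config(cfg)
  # latent normal mean chosen so magnitudes truncated to magnitude_range
  # average magnitude_mean on the observed scale
  cfg$magnitude_latent_mean <- latent_truncnorm_mean(
    cfg$magnitude_mean, cfg$magnitude_sd,
    cfg$magnitude_range[1], cfg$magnitude_range[2]
  )
  structure(cfg, class = "sg_sim_config")
}

# mean of N(mu, s) truncated to [a, b]
truncnorm_mean <- function(mu, s, a, b) {
  al <- (a - mu) / s
  be <- (b - mu) / s
  mu + s * (stats::dnorm(al) - stats::dnorm(be)) /
    (stats::pnorm(be) - stats::pnorm(al))
}

# solve for the latent mu whose truncated mean equals `target`
latent_truncnorm_mean <- function(target, s, a, b) {
  stats::uniroot(function(m) truncnorm_mean(m, s, a, b) - target,
                 interval = c(a - 6 * s, b + 6 * s), tol = 1e-8)$root
}

# rejection-sample one truncated-normal magnitude; NA if bounds infeasible
draw_magnitude <- function(cfg, upper) {
  lo <- cfg$magnitude_range[1]
  hi <- min(cfg$magnitude_range[2], upper)
  if (hi <= lo) return(NA_real_)
  for (i in 1:100) {
    m <- rnorm(1, cfg$magnitude_latent_mean, cfg$magnitude_sd)
    if (m >= lo && m <= hi) return(m)
  }
  NA_real_
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$gain_prevalence, cfg$p_second_gain, cfg$missing_rate,
             cfg$reversal_rate)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (cfg$duration_range[1] < 8 || cfg$duration_range[2] > 30 ||
      cfg$duration_range[1] > cfg$duration_range[2]) {
    abort("duration_range must lie within [8, 30]")
  }
  pos <- c(cfg$baseline_sd_gain, cfg$baseline_sd_nogain, cfg$magnitude_mean,
           cfg$magnitude_sd, cfg$duration_sd, cfg$innovation_sd)
  if (any(pos <= 0)) abort("scale parameters must be positive")
  if (any(cfg$pregain_week_weights < 0) || sum(cfg$pregain_week_weights) <= 0) {
    abort("pregain_week_weights must be non-negative and sum above zero")
  }
  if (abs(cfg$ar_coef) >= 1) abort("ar_coef must lie in (-1, 1)")
  invisible(cfg)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# stationary AR(1) noise of length n
ar1_noise <- function(n, ar, innovation_sd) {
  e <- numeric(n)
  e[1] <- rnorm(1, 0, innovation_sd / sqrt(1 - ar^2))
  for (w in seq_len(n - 1)) e[w + 1] <- ar * e[w] + rnorm(1, 0, innovation_sd)
  e
}

# participant "skeleton": the structural draw (who, when, how big), kept
# fixed while noise realizations are resampled for certification, so the
# certified magnitude distribution stays the one that was drawn
draw_skeleton <- function(cfg, n_gains) {
  duration <- as.integer(round_half_up(rnorm(1, cfg$duration_mean,
                                             cfg$duration_sd)))
  duration <- clamp(duration, cfg$duration_range[1], cfg$duration_range[2])
  if (n_gains == 2L) duration <- max(duration, 14L)

  if (n_gains > 0) {
    baseline <- clamp(rnorm(1, cfg$baseline_mean_gain, cfg$baseline_sd_gain),
                      35, 140)
  } else {
    baseline <- clamp(rnorm(1, cfg$baseline_mean_nogain,
                            cfg$baseline_sd_nogain), 35, 140)
  }
  slope <- max(0, rnorm(1, cfg$slope_mean, cfg$slope_sd))

  # feasible pre-gain weeks need a 2-value post window inside the series
  w <- cfg$pregain_week_weights
  feas <- as.integer(names(w))
  feas_ok <- feas >= 2 & feas <= duration - 2L
  gain_weeks <- integer(0)
  if (n_gains > 0) {
    pool <- feas[feas_ok]
    wts <- w[feas_ok]
    if (length(pool) < n_gains) return(NULL)
    for (try in 1:20) {
      gain_weeks <- sort(sample(pool, n_gains, prob = wts))
      if (n_gains == 1L || diff(gain_weeks) >= 4L) break
      gain_weeks <- integer(0)
    }
    if (!length(gain_weeks)) return(NULL)
  }

  # magnitudes, kept below 75% of the pre-gain level so the scale floor
  # cannot swallow the injected step
  magnitudes <- numeric(0)
  level_drop <- 0
  for (g in gain_weeks) {
    level_at_n <- baseline - slope * (g - 1) - level_drop
    m <- draw_magnitude(cfg, upper = 0.75 * level_at_n)
    if (is.na(m)) return(NULL)
    magnitudes <- c(magnitudes, m)
    level_drop <- level_drop + m
  }

  weeks <- seq_len(duration)
  mu <- baseline - slope * (weeks - 1)
  for (k in seq_along(gain_weeks)) {
    mu[weeks >= gain_weeks[k] + 1L] <- mu[weeks >= gain_weeks[k] + 1L] -
      magnitudes[k]
  }
  if (min(mu) < 2) return(NULL)

  list(duration = duration, baseline = baseline, slope = slope,
       gain_weeks = gain_weeks, magnitudes = magnitudes, mu = mu)
}

# one noise/missingness realization of a skeleton
realize_participant <- function(cfg, sk) {
  duration <- sk$duration
  weeks <- seq_len(duration)
  gain_weeks <- sk$gain_weeks
  magnitudes <- sk$magnitudes
  mu <- sk$mu

  # optional late rebound: a one-week return to 80% of the lost ground,
  # pinned to the post-gain level so it clears the 50%-loss threshold
  if (length(gain_weeks) && cfg$reversal_rate > 0 &&
      runif(1) < cfg$reversal_rate) {
    g1 <- gain_weeks[1]
    if (g1 + 4L <= duration) {
      wr <- sample((g1 + 4L):duration, 1)
      mu[wr] <- sk$mu[g1 + 1L] + 0.8 * magnitudes[1]
    }
  }

  lsas <- clamp(mu + ar1_noise(duration, cfg$ar_coef, cfg$innovation_sd),
                0, 144)

  protected <- unique(c(1L, gain_weeks, gain_weeks + 1L))
  miss <- runif(duration) < cfg$missing_rate & !(weeks %in% protected)
  lsas_obs <- ifelse(miss, NA_real_, lsas)

  # process measures, coupled to the primary (largest) injected gain
  np <- if (length(gain_weeks)) gain_weeks[which.max(magnitudes)] else NA_integer_
  reg <- sg_measures()
  proc <- purrr::pmap_dfr(cfg$process, function(measure, level_mean, level_sd,
                                                slope, noise_sd, drop_pre,
                                                drop_at) {
    rng <- reg[reg$measure == measure, ]
    pm <- rnorm(1, level_mean, level_sd) - slope * (weeks - 1)
    if (!is.na(np)) {
      pm[weeks >= np] <- pm[weeks >= np] - drop_pre
      pm[weeks >= np + 1L] <- pm[weeks >= np + 1L] - drop_at
    }
    v <- clamp(pm + rnorm(duration, 0, noise_sd), rng$min_value, rng$max_value)
    v[runif(duration) < cfg$missing_rate] <- NA_real_
    tibble::tibble(week = weeks, measure = measure, value = v)
  })

  lsas_post <- clamp(mu[duration] + rnorm(1, 0, cfg$innovation_sd), 0, 144)
  lsas_fu3m <- clamp(lsas_post - rnorm(1, 4, 6), 0, 144)

  list(
    trajectory = dplyr::bind_rows(
      tibble::tibble(week = weeks, measure = "lsas", value = lsas_obs),
      proc
    ),
    truth = tibble::tibble(week = gain_weeks, magnitude = magnitudes),
    endpoints = tibble::tibble(lsas_post = lsas_post, lsas_fu3m = lsas_fu3m,
                               baseline_lsas = lsas_obs[1])
  )
}

#' Simulate one participant's trajectory with oracle certification
#'
#' Draws weekly LSAS and process-measure series as a truncated baseline plus
#' gradual linear improvement plus AR(1) noise, with `n_gains` persistent
#' step drops injected for the gain group. The realised (noisy, partially
#' missing) LSAS series is certified by the brute-force [oracle_detect()]:
#' the qualifying intervals must be exactly the injected ones (none, for the
#' no-gain group) and enough LSAS values must be observed to pass the
#' inclusion filter. Draws failing certification are rejected and resampled,
#' up to `config$max_attempts`.
#'
#' @param config An [sim_config()] object.
#' @param group `"gain"` or `"no_gain"`.
#' @param n_gains Number of gains to inject (gain group only; default 1).
#' @return List with `trajectory` (long tibble `week`, `measure`, `value`),
#'   `truth` (tibble `week`, `magnitude` of injected gains), `endpoints`
#'   (one-row tibble `lsas_post`, `lsas_fu3m`, `baseline_lsas`), and
#'   `attempts` used.
#' @export
simulate_trajectory <- function(config, group = c("no_gain", "gain"),
                                n_gains = NULL) {
  group <- match.arg(group)
  validate_sim_config(config)
  n_gains <- as.integer(n_gains %||% if (group == "gain") 1L else 0L)
  if (group == "no_gain") n_gains <- 0L
  stopifnot(n_gains %in% 0:2)

  inner <- max(10L, ceiling(config$max_attempts / 10))
  total <- 0L
  for (sk_try in 1:20) {
    sk <- draw_skeleton(config, n_gains)
    if (is.null(sk)) next
    for (attempt in seq_len(inner)) {
      total <- total + 1L
      if (total > config$max_attempts * 2L) break
      cand <- realize_participant(config, sk)
      lsas <- cand$trajectory$value[cand$trajectory$measure == "lsas"]
      if (sum(!is.na(lsas)) < config$min_lsas_points) next
      found <- oracle_detect(lsas)
      if (length(found) == n_gains && setequal(found, cand$truth$week)) {
        cand$attempts <- total
        return(cand)
      }
    }
  }
  abort(paste0(
    "could not certify a ", group, " trajectory with ", n_gains,
    " gain(s) after ", config$max_attempts, " attempts; ",
    "noise (innovation_sd = ", config$innovation_sd,
    ", ar_coef = ", config$ar_coef, ") or missing_rate (",
    config$missing_rate, ") may be too extreme"
  ))
}

#' Simulate a certified cohort
#'
#' Generates `config$n_participants` trajectories. Gain status is Bernoulli
#' with `gain_prevalence` (second gains with `p_second_gain`) unless an
#' explicit `n_gains` vector fixes each participant's count. Every
#' trajectory is oracle-certified (see [simulate_trajectory()]), so the
#' cohort's qualifying intervals are exactly its ground-truth table.
#'
#' @param config An [sim_config()] object; `config$seed`, when non-NULL, is
#'   set before any draws so equal seeds give bit-identical cohorts.
#' @param n_gains Optional integer vector (length `n_participants`, values
#'   0-2) fixing each participant's injected gain count.
#' @return List of class `sg_sim_cohort`: `cohort` (validated long tibble),
#'   `endpoints` (per-participant tibble), `truth` (tibble
#'   `participant_id`, `week`, `magnitude`), `config`.
#' @export
simulate_cohort <- function(config = sim_config(), n_gains = NULL) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_participants
  if (is.null(n_gains)) {
    has_gain <- rbinom(n, 1, config$gain_prevalence)
    n_gains <- has_gain * (1L + rbinom(n, 1, config$p_second_gain))
  }
  stopifnot(length(n_gains) == n, all(n_gains %in% 0:2))
  ids <- sprintf("P%04d", seq_len(n))

  sims <- purrr::map(seq_len(n), function(i) {
    simulate_trajectory(config,
                        group = if (n_gains[i] > 0) "gain" else "no_gain",
                        n_gains = n_gains[i])
  })

  cohort <- purrr::map2_dfr(sims, ids, function(s, id) {
    dplyr::mutate(s$trajectory, participant_id = id, .before = 1)
  })
  truth <- purrr::map2_dfr(sims, ids, function(s, id) {
    if (nrow(s$truth)) dplyr::mutate(s$truth, participant_id = id, .before = 1)
    else NULL
  })
  if (!nrow(truth)) {
    truth <- tibble::tibble(participant_id = character(), week = integer(),
                            magnitude = double())
  }
  endpoints <- purrr::map2_dfr(sims, ids, function(s, id) {
    dplyr::mutate(s$endpoints, participant_id = id, .before = 1)
  })

  structure(list(
    cohort = validate_cohort(cohort),
    endpoints = endpoints,
    truth = truth,
    config = config
  ), class = "sg_sim_cohort")
}

#' @export
print.sg_sim_cohort <- function(x, ...) {
  cat("Simulated cohort: ", x$config$n_participants, " participants, ",
      dplyr::n_distinct(x$truth$participant_id), " with injected gains (",
      nrow(x$truth), " gains total)\n", sep = "")
  invisible(x)
}

#' Simulate an around-gain panel directly
#'
#' Generates the six-timepoint around-gain panel for one measure straight
#' from the process-coupling parameters (participant intercept + configured
#' drops + observation noise), without simulating full weekly trajectories.
#' Used for power and calibration studies of the process models.
#'
#' @param n Number of participants (gainers).
#' @param measure Measure name (must appear in `config$process`).
#' @param config An [sim_config()] object.
#' @return Around-gain long tibble (`participant_id`, `measure`,
#'   `timepoint`, `week` = NA, `value`).
#' @export
simulate_around_gain <- function(n, measure, config = sim_config()) {
  p <- config$process[config$process$measure == measure, ]
  if (nrow(p) != 1) abort(paste0("no process parameters for '", measure, "'"))
  rng <- sg_measures()
  rng <- rng[rng$measure == measure, ]
  offsets <- c(0, 0, -p$drop_pre, rep(-p$drop_pre - p$drop_at, 3))
  purrr::map_dfr(seq_len(n), function(i) {
    intercept <- rnorm(1, p$level_mean, p$level_sd)
    tibble::tibble(
      participant_id = sprintf("S%04d", i),
      measure = measure,
      timepoint = factor(sg_timepoint_levels, levels = sg_timepoint_levels),
      week = NA_integer_,
      value = clamp(intercept + offsets + rnorm(6, 0, p$noise_sd),
                    rng$min_value, rng$max_value)
    )
  })
}

#' Simulate endpoint data for outcome-model studies
#'
#' Draws per-participant endpoint LSAS scores from the outcome model's own
#' data-generating process (random intercept + baseline covariate +
#' timepoint means + group differences + Gaussian residuals), for parameter
#' recovery, coverage, and type-I-error studies of [fit_outcome_model()].
#' Values are left unclamped so recovery is exact in expectation.
#'
#' @param n Number of participants.
#' @param sg_prob Probability of sudden-gain status.
#' @param diff_post,diff_fu True no-gain-minus-gain differences at
#'   post-intervention and follow-up (0 = null).
#' @param resid_sd Residual SD.
#' @param participant_sd Random-intercept SD.
#' @param baseline_mean,baseline_sd Baseline LSAS distribution.
#' @param baseline_beta True coefficient of baseline on endpoints.
#' @return Endpoints tibble suitable for [fit_outcome_model()].
#' @export
simulate_endpoints <- function(n = 146, sg_prob = 57 / 146,
                               diff_post = 25, diff_fu = 20,
                               resid_sd = 15, participant_sd = 8,
                               baseline_mean = 82.3, baseline_sd = 19.9,
                               baseline_beta = 0.3) {
  sg <- rbinom(n, 1, sg_prob) == 1
  if (all(sg) || !any(sg)) {
    # guarantee both groups at any n
    sg[1] <- TRUE
    sg[2] <- FALSE
  }
  baseline <- rnorm(n, baseline_mean, baseline_sd)
  u <- rnorm(n, 0, participant_sd)
  tibble::tibble(
    participant_id = sprintf("E%04d", seq_len(n)),
    sg = sg,
    baseline_lsas = baseline,
    lsas_post = 45 + baseline_beta * (baseline - baseline_mean) -
      diff_post * sg + u + rnorm(n, 0, resid_sd),
    lsas_fu3m = 38 + baseline_beta * (baseline - baseline_mean) -
      diff_fu * sg + u + rnorm(n, 0, resid_sd)
  )
}
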