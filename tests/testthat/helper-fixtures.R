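# builders for tiny in-code fixtures

lsas_traj <- function(id, values) {
  tibble::tibble(participant_id = id, week = seq_along(values),
                 measure = "lsas", value = values)
}

# the classic stable-flanked 60 -> 40 drop inside a longer series
worked_example_series <- function() {
  c(80, 70, 60, 60, 60, 40, 40, 40, 38, 36)
}

# random short trajectory on a coarse score grid with a few missing weeks
random_short_traj <- function(len = sample(4:12, 1), max_missing = 2) {
  x <- sample(seq(0, 140, by = 10), len, replace = TRUE)
  k <- sample(0:max_missing, 1)
  if (k > 0) x[sample(len, min(k, len))] <- NA
  x
}

# quiet config for fast, well-behaved simulations in tests; overrides win
quiet_config <- function(...) {
  args <- utils::modifyList(
    list(ar_coef = 0.2, innovation_sd = 2.5, missing_rate = 0.05),
    list(...)
  )
  do.call(sim_config, args)
}
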