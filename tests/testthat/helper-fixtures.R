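# Shared fixtures and independent oracles. Everything here is deliberately
# naive (loops, direct arithmetic) so it stays independent of the package's
# vectorised implementations.

# A 10-min temperature series from plain vectors, starting at a given clock
# time on 2017-06-15.
make_series <- function(tsk, ta = 25, bat_id = "B1", start = "00:00:00",
                        included = TRUE, deployment = 1L) {
  n <- length(tsk)
  data.frame(
    bat_id = bat_id, deployment = deployment,
    timestamp = as.POSIXct(paste("2017-06-15", start), tz = "UTC") +
      600 * (seq_len(n) - 1),
    tsk_c = tsk, ta_c = rep_len(ta, n),
    included = rep_len(included, n)
  )
}

# Brute-force torpor oracle: walk the readings one by one, collect maximal
# runs of included sub-threshold readings, keep those of length >= min_run.
brute_torpor <- function(series, threshold, min_run = 3L) {
  runs <- list()
  cur <- integer()
  n <- nrow(series)
  for (i in seq_len(n)) {
    new_seg <- i > 1 && series$deployment[i] != series$deployment[i - 1]
    torpid <- series$included[i] && series$tsk_c[i] < threshold
    if (torpid && !new_seg) {
      cur <- c(cur, i)
    } else {
      if (length(cur) >= min_run) runs[[length(runs) + 1]] <- cur
      cur <- if (torpid) i else integer()
    }
  }
  if (length(cur) >= min_run) runs[[length(runs) + 1]] <- cur
  runs
}

# Random quantized series for oracle-equivalence checks: values on the
# 0.5-grid around a threshold, with random exclusions and deployment splits.
random_series <- function(n = 50) {
  tsk <- round(runif(n, 28, 36) / 0.5) * 0.5
  s <- make_series(tsk, ta = 25)
  s$included <- runif(n) > 0.15
  s$deployment <- cumsum(c(1L, as.integer(runif(n - 1) < 0.05)))
  s
}

# Hand-computed ordered-probit cell probability: number line arithmetic
# written out longhand, independent of the package's matrix code.
hand_cell_prob <- function(t, u, cls, thresholds, sigma_eps) {
  K <- length(thresholds)
  S <- c(1, pnorm((t + u - thresholds) / sigma_eps), 0)
  S[cls + 1] - S[cls + 2]
}

# Minimal two-treatment cohort for model tests.
toy_cohort <- function(n = 6) {
  data.frame(
    bat_id = sprintf("B%02d", seq_len(n)),
    forearm_mm = 44, capture_mass_g = 11,
    treatment = rep(c("T10", "T25"), length.out = n),
    group_id = "g1"
  )
}

# Exam-level dataset drawn from the generative model: n_bats bats, exams
# every 10 days to day 60, covariates N(0,1) and N(0,4), classes 0..3.
simulate_exam_dataset <- function(seed, truth, n_bats = 30) {
  bats <- toy_cohort(n_bats)
  cfg <- sim_config(n_bats = n_bats, truth = truth,
                    n_classes = length(truth$tau) + 2L,
                    monotone = FALSE, seed = seed)
  covars <- expand.grid(bat_id = bats$bat_id, day = seq(0, 60, 10),
                        stringsAsFactors = FALSE)
  set.seed(substream_seed_test(seed, "covars"))
  covars$mass_c <- rnorm(nrow(covars), 0, 1)
  covars$delta_t_c <- rnorm(nrow(covars), 0, 2)
  obs <- simulate_maturation(cfg, bats, covars)
  key <- paste(obs$bat_id, obs$day)
  ckey <- paste(covars$bat_id, covars$day)
  obs$treatment <- bats$treatment[match(obs$bat_id, bats$bat_id)]
  obs$mass_c <- covars$mass_c[match(key, ckey)]
  obs$delta_t_c <- covars$delta_t_c[match(key, ckey)]
  obs
}

# local copy so the helper does not reach into package internals
substream_seed_test <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
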