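test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_bats = 6, seed = 4)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_identical(simulate_tsk(cfg, a$bats[1, ]),
                   simulate_tsk(cfg, a$bats[1, ]))
  covars <- data.frame(bat_id = rep(a$bats$bat_id, 2), day = rep(c(20, 40),
                                                                 each = 6),
                       mass_c = 0, delta_t_c = 0)
  expect_identical(simulate_maturation(cfg, a$bats, covars),
                   simulate_maturation(cfg, a$bats, covars))
})

test_that("cohort respects ranges, groups and noise-free trends", {
  cfg <- sim_config(n_bats = 6, group_size = 3, mass_noise_sd = 0, seed = 8)
  ch <- simulate_cohort(cfg)
  expect_equal(nrow(ch$bats), 6)
  expect_true(all(ch$bats$forearm_mm >= 34 & ch$bats$forearm_mm <= 46.9))
  expect_true(all(ch$bats$capture_mass_g >= 9.4 &
                    ch$bats$capture_mass_g <= 12.8))
  # groups of three within treatment
  sizes <- table(ch$bats$group_id)
  expect_true(all(sizes <= 3))
  expect_equal(length(unique(ch$bats$group_id[ch$bats$treatment == "T25"])),
               ceiling(sum(ch$bats$treatment == "T25") / 3))
  # zero noise: day-0 mass equals capture mass exactly
  d0 <- ch$masses[ch$masses$day == 0, ]
  expect_equal(d0$mass_g[match(ch$bats$bat_id, d0$bat_id)],
               ch$bats$capture_mass_g)
  # masses positive and one record per bat-day over the whole study
  expect_true(all(ch$masses$mass_g > 0))
  expect_equal(nrow(ch$masses), 6 * 63)
  expect_false(anyDuplicated(ch$masses[c("bat_id", "day")]) > 0)
})

test_that("logger traces are quantized, above ambient, and arouse daily", {
  cfg <- sim_config(n_bats = 4, tsk_noise_sd = 0, seed = 6)
  ch <- simulate_cohort(cfg)
  cold <- ch$bats[ch$bats$treatment == "T10", ][1, ]
  warm <- ch$bats[ch$bats$treatment == "T25", ][1, ]
  for (bat in list(cold, warm)) {
    ts <- simulate_tsk(cfg, bat)
    expect_true(all(abs(ts$tsk_c / 0.5 - round(ts$tsk_c / 0.5)) < 1e-9))
    expect_true(all(ts$tsk_c >= ts$ta_c))
    expect_equal(nrow(ts), 62 * 144)
  }
  # noise-free cold trace: exactly one arousal excursion per day
  ts <- simulate_tsk(cfg, cold)
  thr <- torpor_onset_threshold(cold$capture_mass_g, 10)
  day <- rep(seq_len(62), each = 144)
  crossings <- tapply(ts$tsk_c >= thr, day, function(x) {
    sum(diff(c(FALSE, x)) == 1)
  })
  expect_true(all(crossings == 1))
})

test_that("cold-treatment traces yield at least one torpor bout per day", {
  cfg <- sim_config(n_bats = 4, seed = 12)
  ch <- simulate_cohort(cfg)
  cold <- ch$bats[ch$bats$treatment == "T10", ][1, ]
  ts <- simulate_tsk(cfg, cold)
  cfg_s <- study_config(day0 = cfg$day0_date)
  thr <- per_individual_thresholds(ch$bats, ch$masses, cfg_s)
  ev <- detect_torpor_events(ts, thr)
  d <- daily_summaries(ts, ev, cfg_s)
  expect_true(all(d$n_torpor_events >= 1))
})

test_that("deterministic maturation limits follow the thresholds", {
  truth <- sim_truth(tau = c(40, 62, 85), delay = c(30, 35, 0),
                     gamma_mass = rbind(T25 = c(0, 0, 0), T10 = c(0, 0, 0)),
                     gamma_dt = rbind(T25 = c(0, 0, 0), T10 = c(0, 0, 0)),
                     sigma_u = 0, sigma_eps = 0)
  cfg <- sim_config(n_bats = 4, truth = truth, seed = 2)
  bats <- data.frame(bat_id = c("W", "C"), forearm_mm = 44,
                     capture_mass_g = 11, treatment = c("T25", "T10"),
                     group_id = "g")
  covars <- data.frame(bat_id = c("W", "C"), day = 41, mass_c = 0,
                       delta_t_c = 0)
  obs <- simulate_maturation(cfg, bats, covars)
  # day tau_2 + 1: warm bat has crossed transition 2, cold bat has not
  expect_equal(obs$cls[obs$bat_id == "W"], 2L)
  expect_equal(obs$cls[obs$bat_id == "C"], 1L)
})

test_that("monotone post-processing only ever raises later classes", {
  truth <- sim_truth(tau = c(40, 62, 85), delay = c(30, 35, 0),
                     sigma_u = 5, sigma_eps = 8)
  cfg_mono <- sim_config(n_bats = 12, truth = truth, monotone = TRUE,
                         seed = 14)
  cfg_raw <- sim_config(n_bats = 12, truth = truth, monotone = FALSE,
                        seed = 14)
  bats <- toy_cohort(12)
  covars <- expand.grid(bat_id = bats$bat_id, day = seq(0, 60, 10),
                        stringsAsFactors = FALSE)
  covars$mass_c <- 0; covars$delta_t_c <- 0
  mono <- simulate_maturation(cfg_mono, bats, covars)
  raw <- simulate_maturation(cfg_raw, bats, covars)
  expect_true(all(tapply(mono$cls, mono$bat_id,
                         function(x) all(diff(x) >= 0))))
  expect_true(all(mono$cls >= raw$cls))
  expect_equal(mono$cls, as.integer(unlist(
    lapply(split(raw$cls, raw$bat_id), cummax), use.names = FALSE)))
})

test_that("latent transition days are Gaussian with the stated moments", {
  truth <- sim_truth()
  for (trt in c("T25", "T10")) {
    td <- simulate_transition_days(truth, trt, 10000, seed = 9)
    mu <- truth$tau[1] + if (trt == "T10") truth$delay[1] else 0
    sdv <- sqrt(truth$sigma_u^2 + truth$sigma_eps^2)
    ks <- stats::ks.test(td[, 1], "pnorm", mean = mu, sd = sdv)
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("the generating parameters beat perturbed ones in likelihood", {
  truth <- sim_truth(tau = c(40, 62), delay = c(30, 35),
                     gamma_mass = rbind(T25 = c(0, 0), T10 = c(0, 0)),
                     gamma_dt = rbind(T25 = c(0, 0), T10 = c(0, 0)))
  spec <- maturation_spec(n_classes = 4, include_effects = FALSE,
                          impute = FALSE)
  wins <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    ex <- simulate_exam_dataset(100 + r, truth, n_bats = 20)
    ll <- function(tau2_shift) {
      # marginal likelihood proxy: average over u draws at the truth
      set.seed(substream_seed_test(r, "umc"))
      mean(replicate(30, {
        u <- rnorm(20, 0, truth$sigma_u)
        as.numeric(maturation_loglik(
          list(tau = c(40 + tau2_shift, 62), delay = c(30, 35),
               u = u, sigma_u = truth$sigma_u,
               sigma_eps = truth$sigma_eps),
          ex, spec))
      }))
    }
    if (ll(0) > ll(10)) wins <- wins + 1
  }
  expect_gte(wins / n_rep, 0.95)
})

test_that("a simulated study round-trips through the readers", {
  cfg <- sim_config(n_bats = 4, study_days = 10, seed = 19)
  out_dir <- withr::local_tempdir()
  res <- simulate_study(cfg, out_dir)
  expect_error(simulate_study(cfg, out_dir), "already exist")
  bats <- read_cohort(res$paths["cohort"])
  expect_equal(nrow(bats), 4)
  temps <- read_temp_series(res$paths["temps"])
  expect_equal(nrow(temps), 4 * 20 * 144)
  masses <- read_mass_records(res$paths["masses"])
  obs <- read_maturation_obs(res$paths["obs"])
  expect_true(all(obs$cls %in% 0:4))
  tr <- read_truth(res$paths["truth"])
  expect_equal(tr$tau, cfg$truth$tau)
  expect_equal(tr$gamma_dt, cfg$truth$gamma_dt)
  # exam covariates rebuild cleanly from the generated files
  dl <- daily_summaries(apply_exclusions(temps,
                                         study_config()$exclusion_windows),
                        detect_torpor_events(
                          temps, per_individual_thresholds(bats, masses,
                                                           study_config())),
                        study_config(day0 = cfg$day0_date))
  ex <- build_exam_table(obs, masses, dl, bats)
  expect_equal(nrow(ex), nrow(obs))
})
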