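# Small exam table used across the likelihood tests: two bats, one
# treatment each, classes 0..3 (three transitions, first fixed at day 10).
toy_exams <- function() {
  data.frame(bat_id = c("B1", "B2"), day = c(30, 50),
             cls = c(1L, 2L), treatment = c("T25", "T10"),
             mass_c = c(0.5, -0.5), delta_t_c = c(1, -1))
}

toy_params <- function() {
  list(tau = c(40, 62), delay = c(30, 35),
       gamma_mass = rbind(c(-2, -5), c(-11, -7)),
       gamma_dt = rbind(c(1.5, 2.7), c(-5, -5)),
       u = c(2, -3), sigma_u = 5, sigma_eps = 5)
}

test_that("log-likelihood matches longhand ordered-probit arithmetic", {
  ex <- toy_exams()
  p <- toy_params()
  spec <- maturation_spec(n_classes = 4)
  ll <- maturation_loglik(p, ex, spec)
  # independent longhand computation, observation by observation
  thr1 <- c(10,
            40 + (-2) * 0.5 + 1.5 * 1,
            62 + (-5) * 0.5 + 2.7 * 1)
  thr2 <- c(10,
            40 + 30 + (-11) * (-0.5) + (-5) * (-1),
            62 + 35 + (-7) * (-0.5) + (-5) * (-1))
  hand <- log(hand_cell_prob(30, 2, 1, thr1, 5)) +
    log(hand_cell_prob(50, -3, 2, thr2, 5)) +
    dnorm(2, 0, 5, log = TRUE) + dnorm(-3, 0, 5, log = TRUE)
  expect_equal(as.numeric(ll), hand, tolerance = 1e-10)
})

test_that("cell probabilities sum to one over the classes", {
  ex <- toy_exams()
  p <- toy_params()
  p$u <- c(0, 0); p$sigma_u <- 1
  spec <- maturation_spec(n_classes = 4)
  for (row in 1:2) {
    tot <- 0
    for (cls in 0:3) {
      e1 <- ex[row, ]; e1$cls <- cls
      ll <- as.numeric(maturation_loglik(
        list(tau = p$tau, delay = p$delay, gamma_mass = p$gamma_mass,
             gamma_dt = p$gamma_dt, u = 0, sigma_u = 1, sigma_eps = 5),
        e1, spec))
      tot <- tot + exp(ll - dnorm(0, 0, 1, log = TRUE))
    }
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("likelihood limits behave like the deterministic model", {
  spec <- maturation_spec(n_classes = 4, include_effects = FALSE)
  base <- list(tau = c(40, 62), u = 2, sigma_u = 1)
  # exam exactly at a threshold (day 38 + u 2 = tau_2 = 40): P(>= 2) = 0.5
  ex <- data.frame(bat_id = "B1", day = 38, cls = 0L, treatment = "T25",
                   mass_c = 0, delta_t_c = 0)
  p_ge2 <- 0
  for (cls in 2:3) {
    ex$cls <- cls
    ll <- as.numeric(maturation_loglik(c(base, sigma_eps = 5), ex, spec)) -
      dnorm(2, 0, 1, log = TRUE)
    p_ge2 <- p_ge2 + exp(ll)
  }
  expect_equal(p_ge2, 0.5, tolerance = 1e-10)

  # sigma_eps -> 0: the class between tau_2 and tau_3 becomes certain
  ex$cls <- 2L
  ll <- as.numeric(maturation_loglik(c(base, sigma_eps = 1e-6),
                                     transform(ex, day = 50), spec)) -
    dnorm(2, 0, 1, log = TRUE)
  expect_equal(exp(ll), 1, tolerance = 1e-9)
})

test_that("compiled and reference log-posteriors agree", {
  set.seed(42)
  ex <- simulate_exam_dataset(4, sim_truth(tau = c(40, 62),
                                           delay = c(30, 35),
                                           gamma_mass = rbind(T25 = c(0, 0),
                                                              T10 = c(0, 0)),
                                           gamma_dt = rbind(T25 = c(0, 0),
                                                            T10 = c(0, 0))),
                              n_bats = 8)
  ex$mass_c[c(3, 10)] <- NA
  ex$delta_t_c[5] <- NA
  spec <- maturation_spec(n_classes = 4)
  dat <- heterostat:::prep_model_data(ex, spec)
  lay <- heterostat:::model_layout(dat, spec)
  pay <- heterostat:::sampler_payload(dat, spec, lay)
  for (r in 1:25) {
    th <- heterostat:::draw_inits(lay, dat, spec)
    expect_equal(heterostat:::cpp_log_posterior(pay, th),
                 heterostat:::r_log_posterior(th, ex, spec),
                 tolerance = 1e-9)
  }
})

test_that("Gelman-Rubin statistic matches hand arithmetic and detects
           separation", {
  # 2 chains x 4 draws, split into 4 chains of 2: longhand computation
  c1 <- c(1, 2, 3, 4); c2 <- c(2, 2, 4, 6)
  halves <- list(c(1, 2), c(3, 4), c(2, 2), c(4, 6))
  n <- 2
  mns <- sapply(halves, mean)
  W <- mean(sapply(halves, var))
  B <- n * var(mns)
  hand <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(gelman_rubin(cbind(c1, c2)), hand, tolerance = 1e-12)

  # chains that are copies of each other, with identical halves
  x <- rnorm(1e5)
  ch <- c(x, x)
  expect_equal(gelman_rubin(cbind(ch, ch)), 1, tolerance = 1e-5)

  # well-separated chains exceed the 1.1 convergence bound
  set.seed(2)
  expect_gt(gelman_rubin(cbind(rnorm(1000, 0), rnorm(1000, 5))), 1.1)

  # degenerate: zero within-chain variance
  expect_warning(r <- gelman_rubin(cbind(rep(1, 20), rep(1, 20))), "variance")
  expect_equal(r, Inf)
  expect_error(gelman_rubin(matrix(1, 20, 1)), "2 chains")
  expect_error(gelman_rubin(cbind(1:3, 1:3)), "too short")
})

test_that("posterior summaries report quantiles and the significance rule", {
  fake_fit <- function(x, name = "tau[2]") {
    d <- array(x, c(length(x) / 2, 2, 1), dimnames = list(NULL, NULL, name))
    structure(list(draws = d, rhat = stats::setNames(1, name),
                   spec = maturation_spec(), top_class_bats = 5),
              class = "maturation_fit")
  }
  s <- summary(fake_fit(rep(7, 200)))
  expect_equal(s$mean, 7)
  expect_equal(s$sd, 0)
  expect_equal(c(s$q2.5, s$q97.5), c(7, 7))
  expect_true(s$significant)

  sym <- summary(fake_fit(c(seq(-1, 1, length.out = 200))))
  expect_false(sym$significant)

  set.seed(31)
  s3 <- summary(fake_fit(rnorm(10000, 3, 1)))
  expect_equal(s3$q2.5, qnorm(0.025, 3, 1), tolerance = 0.1)
  expect_equal(s3$q97.5, qnorm(0.975, 3, 1), tolerance = 0.1)
  expect_error(summary(fake_fit(rep(1, 50))), "100")
})

test_that("unidentifiable data and bad settings are rejected", {
  ex <- toy_exams()
  ex$cls <- c(1L, 1L)
  expect_error(fit_maturation(ex, maturation_spec(n_classes = 4)),
               "unidentifiable")
  expect_error(fit_maturation(toy_exams(), maturation_spec(n_classes = 4),
                              chains = 1), "chains")
})

test_that("fit recovers a known toy posterior and is deterministic", {
  truth <- sim_truth(tau = c(40, 62), delay = c(30, 35),
                     gamma_mass = rbind(T25 = c(0, 0), T10 = c(0, 0)),
                     gamma_dt = rbind(T25 = c(0, 0), T10 = c(0, 0)))
  ex <- simulate_exam_dataset(21, truth, n_bats = 12)
  spec <- maturation_spec(n_classes = 4, include_effects = FALSE,
                          impute = FALSE)
  fit1 <- suppressWarnings(fit_maturation(ex, spec, chains = 2, iter = 2000,
                                          burnin = 800, thin = 2, seed = 5))
  fit2 <- suppressWarnings(fit_maturation(ex, spec, chains = 2, iter = 2000,
                                          burnin = 800, thin = 2, seed = 5))
  expect_identical(fit1$draws, fit2$draws)  # bit-reproducible
  s <- summary(fit1)
  expect_true(all(c("tau[2]", "tau[3]", "delay[2]", "delay[3]") %in%
                    s$parameter))
  # truth inside broad posterior mass on this small cohort
  expect_lt(abs(s$mean[s$parameter == "tau[2]"] - 40), 10)
})

test_that("posterior shifts with a common shift of days and fixed
           threshold", {
  truth <- sim_truth(tau = c(40, 62), delay = c(30, 35),
                     gamma_mass = rbind(T25 = c(0, 0), T10 = c(0, 0)),
                     gamma_dt = rbind(T25 = c(0, 0), T10 = c(0, 0)))
  ex <- simulate_exam_dataset(13, truth, n_bats = 10)
  cshift <- 15
  ex2 <- ex; ex2$day <- ex2$day + cshift
  spec1 <- maturation_spec(n_classes = 4, include_effects = FALSE,
                           impute = FALSE)
  spec2 <- maturation_spec(n_classes = 4, fixed_day = 10 + cshift,
                           include_effects = FALSE, impute = FALSE)
  f1 <- suppressWarnings(fit_maturation(ex, spec1, chains = 2, iter = 1200,
                                        burnin = 500, thin = 2, seed = 9))
  f2 <- suppressWarnings(fit_maturation(ex2, spec2, chains = 2, iter = 1200,
                                        burnin = 500, thin = 2, seed = 9))
  # increments, effects and RNG streams are identical, so tau shifts exactly
  expect_equal(f2$draws[, , "tau[2]"], f1$draws[, , "tau[2]"] + cshift,
               tolerance = 1e-8)
  expect_equal(f2$draws[, , "tau[3]"], f1$draws[, , "tau[3]"] + cshift,
               tolerance = 1e-8)
})

test_that("imputation machinery is inert when nothing is missing", {
  truth <- sim_truth(tau = c(40, 62), delay = c(30, 35),
                     gamma_mass = rbind(T25 = c(0, 0), T10 = c(0, 0)),
                     gamma_dt = rbind(T25 = c(0, 0), T10 = c(0, 0)))
  ex <- simulate_exam_dataset(17, truth, n_bats = 10)
  stopifnot(!anyNA(ex$mass_c), !anyNA(ex$delta_t_c))
  spec_on <- maturation_spec(n_classes = 4, impute = TRUE)
  spec_off <- maturation_spec(n_classes = 4, impute = FALSE)
  f_on <- suppressWarnings(fit_maturation(ex, spec_on, chains = 2,
                                          iter = 9000, burnin = 3000,
                                          thin = 2, seed = 3))
  f_off <- suppressWarnings(fit_maturation(ex, spec_off, chains = 2,
                                           iter = 9000, burnin = 3000,
                                           thin = 2, seed = 3))
  for (p in c("tau[2]", "tau[3]", "delay[2]")) {
    x_on <- as.vector(f_on$draws[, , p]); x_off <- as.vector(f_off$draws[, , p])
    mcse <- sqrt(sd(x_on)^2 / ess(f_on$draws[, , p]) +
                   sd(x_off)^2 / ess(f_off$draws[, , p]))
    expect_lt(abs(mean(x_on) - mean(x_off)), 2 * mcse + 1e-8)
  }
})

test_that("year-scaled sampling gives the same posterior in days", {
  truth <- sim_truth(tau = c(40, 62), delay = c(30, 35),
                     gamma_mass = rbind(T25 = c(0, 0), T10 = c(0, 0)),
                     gamma_dt = rbind(T25 = c(0, 0), T10 = c(0, 0)))
  ex <- simulate_exam_dataset(23, truth, n_bats = 10)
  sp_d <- maturation_spec(n_classes = 4, include_effects = FALSE,
                          impute = FALSE)
  sp_y <- maturation_spec(n_classes = 4, include_effects = FALSE,
                          impute = FALSE, use_year_scale = TRUE)
  f_d <- suppressWarnings(fit_maturation(ex, sp_d, chains = 2, iter = 3000,
                                         burnin = 1200, thin = 2, seed = 11))
  f_y <- suppressWarnings(fit_maturation(ex, sp_y, chains = 2, iter = 3000,
                                         burnin = 1200, thin = 2, seed = 11))
  # identical model in different units: identical chains up to rounding
  expect_equal(f_y$draws[, , "tau[2]"], f_d$draws[, , "tau[2]"],
               tolerance = 1e-8)
  expect_equal(f_y$draws[, , "sigma_eps"], f_d$draws[, , "sigma_eps"],
               tolerance = 1e-8)
})

test_that("transition-day prediction follows the linear profile rule", {
  truth <- sim_truth(tau = c(40, 62), delay = c(30, 35),
                     gamma_mass = rbind(T25 = c(0, 0), T10 = c(0, 0)),
                     gamma_dt = rbind(T25 = c(0, 0), T10 = c(0, 0)))
  ex <- simulate_exam_dataset(29, truth, n_bats = 10)
  fit <- suppressWarnings(
    fit_maturation(ex, maturation_spec(n_classes = 4), chains = 2,
                   iter = 1500, burnin = 600, thin = 3, seed = 2))
  tau2 <- as.vector(fit$draws[, , "tau[2]"])
  d2 <- as.vector(fit$draws[, , "delay[2]"])
  gm <- as.vector(fit$draws[, , "gamma_mass[T10,2]"])
  base <- predict_transition_days(fit, "T25")
  expect_equal(base[, "T[2]"], tau2)
  cold <- predict_transition_days(fit, "T10")
  expect_equal(cold[, "T[2]"], tau2 + d2)
  heavy <- predict_transition_days(fit, "T10", mass_c = 1)
  expect_equal(heavy[, "T[2]"], tau2 + d2 + gm)
  expect_error(predict_transition_days(fit, "T99"), "unknown treatment")
})
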