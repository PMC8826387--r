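#' Specification of the maturation-timing model
#'
#' The model places the ordinal maturation process on the day axis. A latent
#' maturation time for bat `i` is `t + u_i` (days since capture plus a
#' per-bat random shift); the observed class at an examination is the number
#' of transition thresholds already crossed. The first threshold (class
#' 0 to 1) is fixed at day `fixed_day` (default 10, the treatment onset) and
#' carries no effects. Every later transition `k` has an effective day
#'
#' `T_k = tau_k + delay_k * 1[treatment != baseline] +
#'        gamma_mass[treatment, k] * mass_c + gamma_dt[treatment, k] * dt_c`
#'
#' so baseline transition days, treatment delays and covariate effects are
#' all expressed directly in days. Observation follows a cumulative
#' ordered-probit rule: `P(class >= k) = Phi((t + u_i - T_k) / sigma_eps)`.
#' Baseline ordering `tau_2 < tau_3 < ...` is enforced by sampling positive
#' increments from `fixed_day`.
#'
#' Priors: threshold increments half-Normal(`prior_tau_scale`); treatment
#' delays Normal(0, `prior_delay_sd`^2); covariate effects
#' Normal(0, `prior_effect_sd`^2) in days per centred unit (kept an order
#' of magnitude tighter than the delay prior: a two-sigma effect should
#' not span the whole study); `sigma_u`, `sigma_eps`
#' half-Normal(`prior_sigma_scale`); imputation hyper-means
#' Normal(0, `hyper_mean_sd`^2) and hyper-sds half-Normal(`hyper_sd_scale`)
#' (covariates are centred, so these are weakly informative around the
#' observed means). `prior_rescale` multiplies all prior scales at once for
#' sensitivity runs.
#'
#' @param n_classes number of ordinal classes (default 5, classes 0..4).
#' @param fixed_day day of the fixed first transition (default 10).
#' @param baseline label of the baseline treatment (default "T25").
#' @param include_effects estimate treatment-specific covariate effects?
#' @param impute sample missing covariates from an estimated Gaussian?
#' @param sigma_u,sigma_eps `NULL` to estimate (the default) or a fixed
#'   positive value in days.
#' @param prior_tau_scale,prior_delay_sd,prior_effect_sd,prior_sigma_scale,hyper_mean_sd,hyper_sd_scale
#'   prior scales in days (covariate hyper-scales in covariate units).
#' @param prior_rescale multiplier on all prior scales (sensitivity flag).
#' @param prob_floor floor applied to numerically degenerate cell
#'   probabilities (non-monotone covariate-shifted thresholds); occurrences
#'   are counted and reported on the fit.
#' @param link `"probit"` (Gaussian, the default) or `"logit"`.
#' @param use_year_scale run the sampler on the day/365 axis (data, fixed
#'   threshold and day-unit priors rescaled jointly; draws are always
#'   returned in days). Mathematically equivalent to the default.
#' @return an object of class `maturation_spec`.
#' @export
maturation_spec <- function(n_classes = 5L, fixed_day = 10,
                            baseline = "T25",
                            include_effects = TRUE, impute = TRUE,
                            sigma_u = NULL, sigma_eps = NULL,
                            prior_tau_scale = 50, prior_delay_sd = 50,
                            prior_effect_sd = 15,
                            prior_sigma_scale = 20, hyper_mean_sd = 10,
                            hyper_sd_scale = 10, prior_rescale = 1,
                            prob_floor = 1e-12, link = c("probit", "logit"),
                            use_year_scale = FALSE) {
  stopifnot(n_classes >= 3, prob_floor > 0, prior_rescale > 0)
  if (!is.null(sigma_u)) stopifnot(sigma_u > 0)
  if (!is.null(sigma_eps)) stopifnot(sigma_eps > 0)
  structure(list(
    n_classes = as.integer(n_classes),
    n_trans = as.integer(n_classes) - 1L,
    fixed_day = fixed_day,
    baseline = baseline,
    include_effects = isTRUE(include_effects),
    impute = isTRUE(impute),
    sigma_u = sigma_u, sigma_eps = sigma_eps,
    prior_tau_scale = prior_tau_scale * prior_rescale,
    prior_delay_sd = prior_delay_sd * prior_rescale,
    prior_effect_sd = prior_effect_sd * prior_rescale,
    prior_sigma_scale = prior_sigma_scale * prior_rescale,
    hyper_mean_sd = hyper_mean_sd * prior_rescale,
    hyper_sd_scale = hyper_sd_scale * prior_rescale,
    prob_floor = prob_floor,
    link = match.arg(link),
    use_year_scale = isTRUE(use_year_scale)
  ), class = "maturation_spec")
}

link_cdf <- function(z, link) {
  if (link == "probit") pnorm(z) else stats::plogis(z)
}

# Effective threshold matrix (n_obs x n_trans), in the same day units as t.
# tau: free transition days (k = 2..K); delay: same length (0 if absent);
# gm, gd: 2 x (K-1) matrices (rows baseline/alt) or NULL.
threshold_matrix <- function(fixed_day, tau, delay, gm, gd,
                             treat01, mass, dt) {
  n <- length(treat01)
  K <- length(tau) + 1L
  thr <- matrix(fixed_day, n, K)
  for (k in 2:K) {
    j <- k - 1L
    v <- rep(tau[j], n)
    if (!is.null(delay)) v <- v + delay[j] * treat01
    if (!is.null(gm)) v <- v + gm[cbind(treat01 + 1L, j)] * mass
    if (!is.null(gd)) v <- v + gd[cbind(treat01 + 1L, j)] * dt
    thr[, k] <- v
  }
  thr
}

# Per-observation log cell probabilities under the cumulative model.
# Returns list(logp, n_clipped). Cell probabilities telescope to 1 over
# classes 0..K before clipping.
cell_logprob <- function(t, u_obs, thr, sigma_eps, cls, prob_floor, link) {
  n <- length(t)
  S <- cbind(1, link_cdf((t + u_obs - thr) / sigma_eps, link), 0)
  p <- S[cbind(seq_len(n), cls + 1L)] - S[cbind(seq_len(n), cls + 2L)]
  clipped <- p < prob_floor
  p[clipped] <- prob_floor
  list(logp = log(p), n_clipped = sum(clipped))
}

#' Hierarchical log-likelihood of the maturation model
#'
#' Sum over examinations of the log cell probability under the cumulative
#' ordered model, plus the Gaussian densities of the per-bat random shifts
#' `u_i ~ N(0, sigma_u^2)`, plus — for examinations whose covariate is
#' missing and has an imputed value supplied — the Gaussian imputation
#' densities `N(mu, sd^2)`. This is the reference (pure R) implementation;
#' the sampler uses a compiled equivalent that is cross-checked against it.
#'
#' @param params a list with elements `tau` (free transition days, length
#'   `n_trans - 1`), `delay` (same length; omit or `NULL` for a
#'   single-treatment model), `gamma_mass`, `gamma_dt` (2 x (n_trans-1)
#'   matrices, rows = baseline/non-baseline; `NULL` when effects are off),
#'   `u` (per-bat shifts, in the order of `unique(exams$bat_id)`),
#'   `sigma_u`, `sigma_eps`, and optionally `imp_mass`, `imp_dt` (values
#'   for missing covariates, named by exam row index) with hyper-parameters
#'   `mu_mass`, `sd_mass`, `mu_dt`, `sd_dt`.
#' @param exams examination table from [build_exam_table()] (or any
#'   data.frame with `bat_id, day, cls, treatment, mass_c, delta_t_c`).
#' @param spec a [maturation_spec()].
#' @return scalar log-likelihood; attribute `n_clipped` counts floored
#'   cells.
#' @export
maturation_loglik <- function(params, exams, spec = maturation_spec()) {
  dat <- prep_model_data(exams, spec, require_variation = FALSE)
  K <- spec$n_trans
  tau_abs <- params$tau
  stopifnot(length(tau_abs) == K - 1L, length(params$u) == dat$n_bats)
  mass <- dat$mass; dt <- dat$dt
  ll_imp <- 0
  if (length(dat$miss_m) && !is.null(params$imp_mass)) {
    idx <- as.integer(names(params$imp_mass))
    mass[idx] <- params$imp_mass
    ll_imp <- ll_imp + sum(dnorm(params$imp_mass, params$mu_mass,
                                 params$sd_mass, log = TRUE))
  }
  if (length(dat$miss_d) && !is.null(params$imp_dt)) {
    idx <- as.integer(names(params$imp_dt))
    dt[idx] <- params$imp_dt
    ll_imp <- ll_imp + sum(dnorm(params$imp_dt, params$mu_dt,
                                 params$sd_dt, log = TRUE))
  }
  thr <- threshold_matrix(spec$fixed_day, tau_abs, params$delay %||% NULL,
                          params$gamma_mass %||% NULL,
                          params$gamma_dt %||% NULL,
                          dat$treat01, mass, dt)
  cp <- cell_logprob(dat$t, params$u[dat$bat + 1L], thr, params$sigma_eps,
                     dat$cls, spec$prob_floor, spec$link)
  ll <- sum(cp$logp) +
    sum(dnorm(params$u, 0, params$sigma_u, log = TRUE)) + ll_imp
  attr(ll, "n_clipped") <- cp$n_clipped
  ll
}

# Assemble sampler-ready data from an exam table. Performs the
# identifiability checks and resolves treatment coding (0 = baseline).
prep_model_data <- function(exams, spec, require_variation = TRUE) {
  stopifnot(all(c("bat_id", "day", "cls") %in% names(exams)))
  K <- spec$n_trans
  if (any(exams$cls < 0 | exams$cls > K)) {
    stop("class values outside 0..", K, call. = FALSE)
  }
  if (require_variation && length(unique(exams$cls)) < 2L) {
    stop("all observed classes are identical: transition days are ",
         "unidentifiable", call. = FALSE)
  }
  bats <- unique(exams$bat_id)
  treat_lab <- unique(as.character(exams$treatment))
  treat_lab <- treat_lab[!is.na(treat_lab)]
  base <- spec$baseline
  if (!(base %in% treat_lab)) {
    if (length(treat_lab) == 1L) {
      base <- treat_lab
    } else {
      stop("baseline treatment '", spec$baseline, "' absent from data",
           call. = FALSE)
    }
  }
  alt <- setdiff(treat_lab, base)
  if (length(alt) > 1L) stop("more than two treatments", call. = FALSE)
  treat01 <- as.integer(as.character(exams$treatment) %in% alt)
  mass <- exams$mass_c %||% rep(0, nrow(exams))
  dt <- exams$delta_t_c %||% rep(0, nrow(exams))
  miss_m <- which(is.na(mass)); miss_d <- which(is.na(dt))
  mass[miss_m] <- 0; dt[miss_d] <- 0
  bat_idx <- match(exams$bat_id, bats) - 1L
  list(
    t = as.numeric(exams$day), bat = bat_idx, treat01 = treat01,
    cls = as.integer(exams$cls), mass = as.numeric(mass),
    dt = as.numeric(dt), miss_m = miss_m, miss_d = miss_d,
    n_bats = length(bats), bat_ids = bats,
    baseline = base, alt = if (length(alt)) alt else NA_character_,
    est_delay = length(alt) == 1L,
    obs_by_bat = lapply(seq_along(bats) - 1L,
                        function(i) which(bat_idx == i) - 1L),
    top_class_bats = length(unique(exams$bat_id[exams$cls == K]))
  )
}
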