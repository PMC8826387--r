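# Parameter-vector layout shared between the R side and the compiled
# sampler. All offsets are 0-based; -1 marks an absent block.
model_layout <- function(dat, spec) {
  K <- spec$n_trans
  nf <- K - 1L
  est_cov <- spec$include_effects
  est_su <- is.null(spec$sigma_u)
  est_se <- is.null(spec$sigma_eps)
  impute <- spec$impute && est_cov
  n_im <- if (impute) length(dat$miss_m) else 0L
  n_id <- if (impute) length(dat$miss_d) else 0L
  nm <- paste0("e[", 2:K, "]")
  off <- list(e = 0L, d = -1L, gm0 = -1L, gm1 = -1L, gd0 = -1L, gd1 = -1L,
              u = -1L, lsu = -1L, lse = -1L, hyper = -1L,
              im = -1L, id = -1L)
  pos <- nf
  lab1 <- dat$baseline
  lab2 <- if (is.na(dat$alt)) "alt" else dat$alt
  if (dat$est_delay) {
    off$d <- pos; pos <- pos + nf
    nm <- c(nm, paste0("delay[", 2:K, "]"))
  }
  if (est_cov) {
    off$gm0 <- pos; pos <- pos + nf
    off$gm1 <- pos; pos <- pos + nf
    off$gd0 <- pos; pos <- pos + nf
    off$gd1 <- pos; pos <- pos + nf
    nm <- c(nm,
            paste0("gamma_mass[", lab1, ",", 2:K, "]"),
            paste0("gamma_mass[", lab2, ",", 2:K, "]"),
            paste0("gamma_dt[", lab1, ",", 2:K, "]"),
            paste0("gamma_dt[", lab2, ",", 2:K, "]"))
  }
  off$u <- pos; pos <- pos + dat$n_bats
  nm <- c(nm, paste0("u[", dat$bat_ids, "]"))
  if (est_su) { off$lsu <- pos; pos <- pos + 1L; nm <- c(nm, "log_sigma_u") }
  if (est_se) {
    off$lse <- pos; pos <- pos + 1L; nm <- c(nm, "log_sigma_eps")
  }
  if (impute) {
    off$hyper <- pos; pos <- pos + 4L
    nm <- c(nm, "mu_mass", "log_sd_mass", "mu_dt", "log_sd_dt")
    if (n_im) {
      off$im <- pos; pos <- pos + n_im
      nm <- c(nm, paste0("imp_mass[", dat$miss_m, "]"))
    }
    if (n_id) {
      off$id <- pos; pos <- pos + n_id
      nm <- c(nm, paste0("imp_dt[", dat$miss_d, "]"))
    }
  }
  list(names = nm, off = off, npar = pos, K = K, nf = nf,
       est_cov = est_cov, est_su = est_su, est_se = est_se,
       impute = impute, n_im = n_im, n_id = n_id)
}

# Random initial values drawn from the priors (day-scale; the caller
# rescales when year-scaling is on). Scales are floored away from zero for
# the variance components so no chain starts in a degenerate likelihood.
draw_inits <- function(lay, dat, spec) {
  th <- numeric(lay$npar)
  th[seq_len(lay$nf)] <- pmax(abs(rnorm(lay$nf, 0, spec$prior_tau_scale)), 1)
  if (lay$off$d >= 0) {
    th[lay$off$d + seq_len(lay$nf)] <- rnorm(lay$nf, 0, spec$prior_delay_sd)
  }
  if (lay$est_cov) {
    for (o in c(lay$off$gm0, lay$off$gm1, lay$off$gd0, lay$off$gd1)) {
      th[o + seq_len(lay$nf)] <- rnorm(lay$nf, 0, spec$prior_effect_sd)
    }
  }
  su <- spec$sigma_u %||% pmax(abs(rnorm(1, 0, spec$prior_sigma_scale)), 0.5)
  th[lay$off$u + seq_len(dat$n_bats)] <- rnorm(dat$n_bats, 0, su)
  if (lay$est_su) th[lay$off$lsu + 1L] <- log(su)
  if (lay$est_se) {
    th[lay$off$lse + 1L] <-
      log(pmax(abs(rnorm(1, 0, spec$prior_sigma_scale)), 0.5))
  }
  if (lay$impute) {
    h <- lay$off$hyper
    th[h + 1L] <- rnorm(1, 0, spec$hyper_mean_sd)
    th[h + 2L] <- log(pmax(abs(rnorm(1, 0, spec$hyper_sd_scale)), 0.2))
    th[h + 3L] <- rnorm(1, 0, spec$hyper_mean_sd)
    th[h + 4L] <- log(pmax(abs(rnorm(1, 0, spec$hyper_sd_scale)), 0.2))
    if (lay$n_im) {
      th[lay$off$im + seq_len(lay$n_im)] <-
        rnorm(lay$n_im, th[h + 1L], exp(th[h + 2L]))
    }
    if (lay$n_id) {
      th[lay$off$id + seq_len(lay$n_id)] <-
        rnorm(lay$n_id, th[h + 3L], exp(th[h + 4L]))
    }
  }
  th
}

# Initial random-walk step sizes by block, tuned further by the sampler's
# burn-in adaptation.
init_steps <- function(lay, dat) {
  st <- numeric(lay$npar)
  st[seq_len(lay$nf)] <- 5
  if (lay$off$d >= 0) st[lay$off$d + seq_len(lay$nf)] <- 5
  if (lay$est_cov) {
    for (o in c(lay$off$gm0, lay$off$gm1, lay$off$gd0, lay$off$gd1)) {
      st[o + seq_len(lay$nf)] <- 2
    }
  }
  st[lay$off$u + seq_len(dat$n_bats)] <- 3
  if (lay$est_su) st[lay$off$lsu + 1L] <- 0.3
  if (lay$est_se) st[lay$off$lse + 1L] <- 0.3
  if (lay$impute) {
    st[lay$off$hyper + 1:4] <- 0.5
    if (lay$n_im) st[lay$off$im + seq_len(lay$n_im)] <- 1
    if (lay$n_id) st[lay$off$id + seq_len(lay$n_id)] <- 1
  }
  st
}

# Bundle everything the compiled chain needs. `s` is the time-scale factor
# (1 or 1/365): day-valued data and day-unit prior scales are multiplied by
# it so the two settings are the same model in different units.
sampler_payload <- function(dat, spec, lay) {
  s <- if (spec$use_year_scale) 1 / 365 else 1
  list(
    t = dat$t * s, bat = dat$bat, treat = dat$treat01, cls = dat$cls,
    mass = dat$mass, dt = dat$dt,
    miss_m = dat$miss_m - 1L, miss_d = dat$miss_d - 1L,
    obs_by_bat = dat$obs_by_bat,
    n_bats = dat$n_bats, K = lay$K, fixed_day = spec$fixed_day * s,
    est_delay = as.integer(dat$est_delay),
    est_cov = as.integer(lay$est_cov),
    est_su = as.integer(lay$est_su), est_se = as.integer(lay$est_se),
    impute = as.integer(lay$impute),
    su_fix = (spec$sigma_u %||% 0) * s, se_fix = (spec$sigma_eps %||% 0) * s,
    p_tau = spec$prior_tau_scale * s, p_del = spec$prior_delay_sd * s,
    p_eff = spec$prior_effect_sd * s,
    p_sig = spec$prior_sigma_scale * s,
    h_mu_sd = spec$hyper_mean_sd, h_sd_scale = spec$hyper_sd_scale,
    prob_floor = spec$prob_floor,
    link = if (spec$link == "probit") 0L else 1L,
    off = lay$off, npar = lay$npar, s = s
  )
}

# Indices (1-based) of day-unit parameters inside the raw theta vector,
# used to undo year-scaling on the draws.
day_unit_cols <- function(lay, dat) {
  idx <- seq_len(lay$nf)
  if (lay$off$d >= 0) idx <- c(idx, lay$off$d + seq_len(lay$nf))
  if (lay$est_cov) {
    for (o in c(lay$off$gm0, lay$off$gm1, lay$off$gd0, lay$off$gd1)) {
      idx <- c(idx, o + seq_len(lay$nf))
    }
  }
  c(idx, lay$off$u + seq_len(dat$n_bats))
}

# Pure-R replica of the sampler's joint log-posterior (day units, no year
# scaling), built on the reference likelihood. Used to validate the
# compiled implementation; not part of the sampling path.
r_log_posterior <- function(theta, exams, spec) {
  dat <- prep_model_data(exams, spec, require_variation = FALSE)
  lay <- model_layout(dat, spec)
  stopifnot(length(theta) == lay$npar)
  nf <- lay$nf
  half_lp <- function(x, scale) {
    if (any(x <= 0)) return(-Inf)
    sum(dnorm(x, 0, scale, log = TRUE))
  }
  e <- theta[seq_len(nf)]
  p <- list(tau = spec$fixed_day + cumsum(e))
  lp <- half_lp(e, spec$prior_tau_scale)
  if (!is.finite(lp)) return(-Inf)
  if (lay$off$d >= 0) {
    p$delay <- theta[lay$off$d + seq_len(nf)]
    lp <- lp + sum(dnorm(p$delay, 0, spec$prior_delay_sd, log = TRUE))
  }
  if (lay$est_cov) {
    g <- lapply(c(lay$off$gm0, lay$off$gm1, lay$off$gd0, lay$off$gd1),
                function(o) theta[o + seq_len(nf)])
    p$gamma_mass <- rbind(g[[1]], g[[2]])
    p$gamma_dt <- rbind(g[[3]], g[[4]])
    lp <- lp + sum(dnorm(unlist(g), 0, spec$prior_effect_sd, log = TRUE))
  }
  p$u <- theta[lay$off$u + seq_len(dat$n_bats)]
  p$sigma_u <- if (lay$est_su) exp(theta[lay$off$lsu + 1L]) else spec$sigma_u
  p$sigma_eps <- if (lay$est_se) exp(theta[lay$off$lse + 1L])
                 else spec$sigma_eps
  if (lay$est_su) {
    lp <- lp + half_lp(p$sigma_u, spec$prior_sigma_scale) +
      theta[lay$off$lsu + 1L]
  }
  if (lay$est_se) {
    lp <- lp + half_lp(p$sigma_eps, spec$prior_sigma_scale) +
      theta[lay$off$lse + 1L]
  }
  if (lay$impute) {
    h <- lay$off$hyper
    p$mu_mass <- theta[h + 1L]; p$sd_mass <- exp(theta[h + 2L])
    p$mu_dt <- theta[h + 3L]; p$sd_dt <- exp(theta[h + 4L])
    lp <- lp + dnorm(p$mu_mass, 0, spec$hyper_mean_sd, log = TRUE) +
      half_lp(p$sd_mass, spec$hyper_sd_scale) + theta[h + 2L] +
      dnorm(p$mu_dt, 0, spec$hyper_mean_sd, log = TRUE) +
      half_lp(p$sd_dt, spec$hyper_sd_scale) + theta[h + 4L]
    obs_m <- dat$mass[setdiff(seq_along(dat$mass), dat$miss_m)]
    obs_d <- dat$dt[setdiff(seq_along(dat$dt), dat$miss_d)]
    lp <- lp + sum(dnorm(obs_m, p$mu_mass, p$sd_mass, log = TRUE)) +
      sum(dnorm(obs_d, p$mu_dt, p$sd_dt, log = TRUE))
    if (lay$n_im) {
      v <- theta[lay$off$im + seq_len(lay$n_im)]
      names(v) <- dat$miss_m
      p$imp_mass <- v
    }
    if (lay$n_id) {
      v <- theta[lay$off$id + seq_len(lay$n_id)]
      names(v) <- dat$miss_d
      p$imp_dt <- v
    }
  }
  lp + as.numeric(maturation_loglik(p, exams, spec))
}

#' Fit the hierarchical maturation-timing model
#'
#' Seeded multi-chain adaptive Metropolis-within-Gibbs sampling of the
#' model described in [maturation_spec()]. Each chain starts from random
#' initial values drawn from the priors; proposal step sizes adapt during
#' burn-in only (target acceptance 0.44), so retained draws come from a
#' fixed kernel. Missing covariates are sampled jointly with the model
#' parameters. Convergence is assessed per parameter with the
#' Gelman-Rubin statistic; a fit with any `Rhat >= 1.1` is flagged (and
#' warned about), never suppressed.
#'
#' @param exams examination table from [build_exam_table()].
#' @param spec a [maturation_spec()].
#' @param chains,iter,burnin,thin sampler settings; the study-scale defaults
#'   are 3 chains of 50000 iterations, 20000 burn-in, thinning by 3.
#' @param seed root seed; each chain uses a derived sub-seed, so results are
#'   reproducible bit-for-bit on one platform.
#' @return an object of class `maturation_fit`: draws (day units) as a
#'   `[draw, chain, parameter]` array, per-parameter `rhat`, acceptance
#'   rates, the count of floored cell probabilities, and metadata.
#' @export
fit_maturation <- function(exams, spec = maturation_spec(), chains = 3L,
                           iter = 50000L, burnin = 20000L, thin = 3L,
                           seed = 1L) {
  chains <- as.integer(chains); iter <- as.integer(iter)
  burnin <- as.integer(burnin); thin <- as.integer(thin)
  stopifnot(chains >= 2, iter > burnin, thin >= 1)
  dat <- prep_model_data(exams, spec)
  per_trt <- table(unique(exams[c("bat_id", "treatment")])$treatment)
  if (any(per_trt < 2)) {
    warning("fewer than 2 bats in some treatment; delay weakly identified")
  }
  lay <- model_layout(dat, spec)
  pay <- sampler_payload(dat, spec, lay)
  steps <- init_steps(lay, dat)
  dcs <- day_unit_cols(lay, dat)
  steps[dcs] <- steps[dcs] * pay$s  # log-scale and covariate steps unscaled
  n_keep <- floor((iter - burnin) / thin)
  draws <- array(NA_real_, c(n_keep, chains, lay$npar),
                 dimnames = list(NULL, NULL, lay$names))
  accept <- matrix(NA_real_, chains, lay$npar)
  n_clipped <- 0
  for (ch in seq_len(chains)) {
    set.seed(substream_seed(seed, paste0("mcmc_chain_", ch)))
    init <- draw_inits(lay, dat, spec)
    init[day_unit_cols(lay, dat)] <- init[day_unit_cols(lay, dat)] * pay$s
    if (lay$est_su) init[lay$off$lsu + 1L] <-
      init[lay$off$lsu + 1L] + log(pay$s)
    if (lay$est_se) init[lay$off$lse + 1L] <-
      init[lay$off$lse + 1L] + log(pay$s)
    res <- run_mcmc_chain(pay, init, steps, as.integer(iter),
                          as.integer(burnin), as.integer(thin))
    draws[, ch, ] <- res$draws
    accept[ch, ] <- res$accept
    n_clipped <- n_clipped + res$n_clipped
  }
  # back to day units
  dc <- day_unit_cols(lay, dat)
  draws[, , dc] <- draws[, , dc, drop = FALSE] / pay$s
  if (lay$est_su) draws[, , lay$off$lsu + 1L] <-
    draws[, , lay$off$lsu + 1L] - log(pay$s)
  if (lay$est_se) draws[, , lay$off$lse + 1L] <-
    draws[, , lay$off$lse + 1L] - log(pay$s)
  der <- derive_draws(draws, lay, dat, spec)
  rhat <- apply(der, 3, function(m) gelman_rubin(m))
  names(rhat) <- dimnames(der)[[3]]
  fit <- structure(list(
    draws = der, raw_names = lay$names,
    rhat = rhat, accept = accept, n_clipped = n_clipped,
    spec = spec, layout = lay,
    bat_ids = dat$bat_ids, baseline = dat$baseline, alt = dat$alt,
    top_class_bats = dat$top_class_bats,
    centers = c(mass = attr(exams, "mass_center") %||% NA_real_,
                delta_t = attr(exams, "delta_t_center") %||% NA_real_),
    settings = list(chains = chains, iter = iter, burnin = burnin,
                    thin = thin, seed = seed),
    converged = all(is.finite(rhat) & rhat < 1.1)
  ), class = "maturation_fit")
  if (!fit$converged) {
    warning("some Rhat >= 1.1: chains have not converged; ",
            "results are flagged, inspect $rhat")
  }
  fit
}

# Transform raw sampler draws to the reported scale: absolute transition
# days tau_k (= fixed day + cumulative increments), sigmas on the natural
# scale, everything else unchanged.
derive_draws <- function(draws, lay, dat, spec) {
  nm <- lay$names
  K <- lay$K
  out_nm <- nm
  out <- draws
  e_idx <- seq_len(lay$nf)
  if (lay$nf > 1) {
    for (k in 2:lay$nf) {
      out[, , e_idx[k]] <- out[, , e_idx[k - 1]] + draws[, , e_idx[k]]
    }
  }
  out[, , e_idx] <- out[, , e_idx, drop = FALSE] + spec$fixed_day
  out_nm[e_idx] <- paste0("tau[", 2:K, "]")
  if (lay$est_su) {
    i <- lay$off$lsu + 1L
    out[, , i] <- exp(draws[, , i]); out_nm[i] <- "sigma_u"
  }
  if (lay$est_se) {
    i <- lay$off$lse + 1L
    out[, , i] <- exp(draws[, , i]); out_nm[i] <- "sigma_eps"
  }
  if (lay$impute) {
    h <- lay$off$hyper
    out[, , h + 2L] <- exp(draws[, , h + 2L])
    out[, , h + 4L] <- exp(draws[, , h + 4L])
    out_nm[h + 2L] <- "sd_mass"; out_nm[h + 4L] <- "sd_dt"
  }
  dimnames(out)[[3]] <- out_nm
  out
}

#' @export
print.maturation_fit <- function(x, ...) {
  st <- x$settings
  cat("Hierarchical maturation-timing fit\n")
  cat(sprintf("  bats: %d  transitions: %d (first fixed at day %g)\n",
              length(x$bat_ids), x$spec$n_trans, x$spec$fixed_day))
  cat(sprintf("  chains: %d x %d iterations (burn-in %d, thin %d)\n",
              st$chains, st$iter, st$burnin, st$thin))
  cat(sprintf("  max Rhat: %.3f (%s)\n", max(x$rhat),
              if (x$converged) "converged" else "NOT converged"))
  if (x$n_clipped > 0) {
    cat(sprintf("  floored cell probabilities: %d\n", x$n_clipped))
  }
  invisible(x)
}

#' Posterior summary table
#'
#' One row per reported parameter: posterior mean, sd, 2.5/50/97.5
#' percentiles (linear interpolation), Gelman-Rubin statistic, and the
#' significance flag (`TRUE` when the central 95% credible interval
#' excludes 0). Transition days, delays and effects are in days. The
#' highest transition is only reported when at least 2 bats were observed
#' in the top class — with fewer, its posterior reflects the prior rather
#' than the data.
#'
#' @param object a `maturation_fit`.
#' @param report_random include per-bat random shifts `u`?
#' @param report_all_transitions report the top transition regardless of
#'   data support?
#' @param ... unused.
#' @return data.frame `parameter, mean, sd, q2.5, q50, q97.5, rhat,
#'   significant`.
#' @export
summary.maturation_fit <- function(object, report_random = FALSE,
                                   report_all_transitions = FALSE, ...) {
  d <- object$draws
  if (dim(d)[1] * dim(d)[2] < 100) {
    stop("fewer than 100 retained draws; increase iterations", call. = FALSE)
  }
  nm <- dimnames(d)[[3]]
  K <- object$spec$n_trans
  keep <- !grepl("^(u\\[|imp_)", nm)
  if (report_random) keep <- keep | grepl("^u\\[", nm)
  if (!report_all_transitions && object$top_class_bats < 2) {
    keep <- keep & !grepl(paste0("\\[.*", K, "\\]$"), nm)
  }
  rows <- lapply(which(keep), function(i) {
    x <- as.vector(d[, , i])
    q <- quantile(x, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    data.frame(parameter = nm[i], mean = mean(x), sd = sd(x),
               q2.5 = q[1], q50 = q[2], q97.5 = q[3],
               rhat = unname(object$rhat[nm[i]]),
               significant = q[1] > 0 | q[3] < 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior of effective transition days for a covariate profile
#'
#' For a given treatment and centred covariate values, returns draws of the
#' effective transition day `T_k = tau_k + delay_k * 1[non-baseline] +
#' gamma_mass[g,k] * mass_c + gamma_dt[g,k] * delta_t_c` for every free
#' transition. The baseline profile (baseline treatment, covariates 0) is
#' the posterior of `tau_k` itself.
#'
#' @param fit a `maturation_fit`.
#' @param treatment treatment label.
#' @param mass_c,delta_t_c centred covariate values (default 0).
#' @return matrix of draws, one column per transition (`T[k]`).
#' @export
predict_transition_days <- function(fit, treatment, mass_c = 0,
                                    delta_t_c = 0) {
  nm <- dimnames(fit$draws)[[3]]
  K <- fit$spec$n_trans
  known <- c(fit$baseline, if (!is.na(fit$alt)) fit$alt)
  if (!(treatment %in% known)) {
    stop("unknown treatment '", treatment, "'", call. = FALSE)
  }
  is_alt <- !is.na(fit$alt) && treatment == fit$alt
  flat <- function(p) {
    if (!(p %in% nm)) return(0)
    as.vector(fit$draws[, , p])
  }
  out <- sapply(2:K, function(k) {
    v <- flat(paste0("tau[", k, "]"))
    if (is_alt) v <- v + flat(paste0("delay[", k, "]"))
    v <- v + mass_c * flat(paste0("gamma_mass[", treatment, ",", k, "]"))
    v + delta_t_c * flat(paste0("gamma_dt[", treatment, ",", k, "]"))
  })
  colnames(out) <- paste0("T[", 2:K, "]")
  out
}
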