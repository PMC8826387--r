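#' True generating parameters for a synthetic study
#'
#' Defaults are the study-scale estimates for the first two free
#' transitions (baseline days 39.37 and 62.81 since capture; cold-treatment
#' delays 33.48 and 37.12 days; mass and delta-T effects in days per
#' centred unit). The last transition (class 3 to 4, testis regression) was
#' not estimable in the source study, so its defaults are nominal
#' placeholders: a late baseline day and zero effects.
#'
#' @param tau baseline transition days (transitions 2..K), strictly
#'   increasing and above the fixed day-10 first transition.
#' @param delay non-baseline treatment delays in days, same length.
#' @param gamma_mass,gamma_dt 2 x length(tau) matrices of covariate effects
#'   (days per centred unit), rows `T25` (baseline) and `T10`.
#' @param sigma_u between-bat sd of the random timing shift (days).
#' @param sigma_eps observation noise sd on the latent day axis (days).
#' @return a list of class `sim_truth`.
#' @export
sim_truth <- function(tau = c(39.37, 62.81, 85),
                      delay = c(33.48, 37.12, 0),
                      gamma_mass = rbind(T25 = c(-2.19, -5.89, 0),
                                         T10 = c(-11.9, -7.54, 0)),
                      gamma_dt = rbind(T25 = c(1.63, 2.72, 0),
                                       T10 = c(-5.38, -5.32, 0)),
                      sigma_u = 5, sigma_eps = 5) {
  stopifnot(all(diff(c(10, tau)) > 0), length(delay) == length(tau),
            ncol(gamma_mass) == length(tau), ncol(gamma_dt) == length(tau),
            sigma_u >= 0, sigma_eps >= 0)
  structure(list(tau = tau, delay = delay, gamma_mass = gamma_mass,
                 gamma_dt = gamma_dt, sigma_u = sigma_u,
                 sigma_eps = sigma_eps), class = "sim_truth")
}

#' Configuration of a synthetic study
#'
#' Emulates the field experiment: a cohort captured in mid-June, 10 days of
#' acclimation, then 52 days under two ambient-temperature treatments (10
#' and 25 deg C) in groups of three, daily mass records, 10-minute
#' skin-temperature logger traces and ordinal maturation examinations every
#' 10 days drawn from the transition-time model itself.
#'
#' @param n_bats cohort size (default 36, at least 4).
#' @param group_size housing-group size (default 3).
#' @param study_days length of the treatment phase in days (default 52).
#' @param acclimation_days days between capture and treatment onset
#'   (default 10; day numbering starts at capture = day 0).
#' @param exam_interval days between maturation examinations (default 10).
#' @param treatments named ambient temperatures in deg C.
#' @param capture_mass_range,forearm_range uniform sampling ranges for
#'   capture mass (g) and forearm length (mm), matching the field cohort
#'   (9.4-12.8 g, 34.0-46.9 mm).
#' @param truth a [sim_truth()].
#' @param n_classes ordinal classes (default 5; `length(truth$tau)` must be
#'   `n_classes - 2`).
#' @param mass_noise_sd daily mass noise sd in g.
#' @param tsk_noise_sd logger noise sd in deg C (before 0.5-quantization).
#' @param normothermic_c skin temperature during arousals, deg C.
#' @param torpid_offset_c skin-over-ambient offset while torpid, deg C.
#' @param arousal_hour,arousal_len_min daily evening arousal clock hour and
#'   length in minutes (cold treatment: one arousal per day).
#' @param t25_band daytime fluctuation band for warm-treatment skin
#'   temperature, deg C.
#' @param t25_arousals_per_day brief normothermic excursions per day in the
#'   warm treatment (breaks torpor bouts; free shape knob, not an
#'   estimate).
#' @param day0_date calendar date of capture.
#' @param monotone force classes to be non-decreasing over a bat's exams
#'   (default `TRUE`; disable for likelihood-consistency checks).
#' @param seed root seed; every stage draws from a named substream.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_bats = 36L, group_size = 3L, study_days = 52L,
                       acclimation_days = 10L, exam_interval = 10L,
                       treatments = c(T10 = 10, T25 = 25),
                       capture_mass_range = c(9.4, 12.8),
                       forearm_range = c(34.0, 46.9),
                       truth = sim_truth(), n_classes = 5L,
                       mass_noise_sd = 0.2, tsk_noise_sd = 0.3,
                       normothermic_c = 33, torpid_offset_c = 0.7,
                       arousal_hour = 18, arousal_len_min = 60,
                       t25_band = c(24.2, 30.6), t25_arousals_per_day = 2,
                       day0_date = as.Date("2017-06-15"),
                       monotone = TRUE, seed = 1L) {
  stopifnot(n_bats >= 4, group_size >= 1, mass_noise_sd >= 0,
            tsk_noise_sd >= 0,
            length(truth$tau) == n_classes - 2L)
  structure(list(
    n_bats = as.integer(n_bats), group_size = as.integer(group_size),
    study_days = as.integer(study_days),
    acclimation_days = as.integer(acclimation_days),
    exam_interval = as.integer(exam_interval),
    treatments = treatments,
    capture_mass_range = capture_mass_range,
    forearm_range = forearm_range,
    truth = truth, n_classes = as.integer(n_classes),
    mass_noise_sd = mass_noise_sd, tsk_noise_sd = tsk_noise_sd,
    normothermic_c = normothermic_c, torpid_offset_c = torpid_offset_c,
    arousal_hour = arousal_hour, arousal_len_min = arousal_len_min,
    t25_band = t25_band, t25_arousals_per_day = t25_arousals_per_day,
    day0_date = as.Date(day0_date), monotone = isTRUE(monotone),
    seed = as.integer(seed)
  ), class = "sim_config")
}

total_days <- function(cfg) cfg$acclimation_days + cfg$study_days

#' Simulate a cohort with mass trajectories
#'
#' Forearm length and capture mass are drawn uniformly in the configured
#' field ranges; treatments are assigned balanced on body condition
#' ([assign_treatments()]); housing groups of `group_size` are formed
#' within treatment. Daily masses follow a piecewise-linear
#' treatment-specific trend (warm: dip then slow recovery; cold: brief rise
#' then steady decline) plus Gaussian noise.
#'
#' @param cfg a [sim_config()].
#' @return list with `bats` (cohort data.frame) and `masses` (daily mass
#'   records).
#' @export
simulate_cohort <- function(cfg) {
  set.seed(substream_seed(cfg$seed, "cohort"))
  n <- cfg$n_bats
  bats <- data.frame(
    bat_id = sprintf("B%02d", seq_len(n)),
    forearm_mm = runif(n, cfg$forearm_range[1], cfg$forearm_range[2]),
    capture_mass_g = runif(n, cfg$capture_mass_range[1],
                           cfg$capture_mass_range[2]),
    treatment = NA_character_, group_id = NA_character_
  )
  bats <- assign_treatments(bats, seed = cfg$seed,
                            labels = names(cfg$treatments))
  for (tr in unique(bats$treatment)) {
    i <- which(bats$treatment == tr)
    bats$group_id[i] <- paste0(tr, "_g", ceiling(seq_along(i) /
                                                   cfg$group_size))
  }
  nd <- total_days(cfg)
  set.seed(substream_seed(cfg$seed, "masses"))
  masses <- do.call(rbind, lapply(seq_len(n), function(i) {
    m0 <- bats$capture_mass_g[i]
    day <- 0:nd
    trend <- if (bats$treatment[i] == names(cfg$treatments)[2]) {
      # warm arm: decline over first 20 days, then slow recovery
      ifelse(day <= 20, m0 - 1.2 * day / 20,
             m0 - 1.2 + 1.2 * (day - 20) / (nd - 20))
    } else {
      # cold arm: small rise to day 17, then steady decline
      ifelse(day <= 17, m0 + 0.3 * day / 17,
             m0 + 0.3 - 1.3 * (day - 17) / (nd - 17))
    }
    data.frame(bat_id = bats$bat_id[i], day = day,
               mass_g = pmax(trend + rnorm(length(day), 0, cfg$mass_noise_sd),
                             0.1))
  }))
  rownames(masses) <- NULL
  list(bats = bats, masses = masses)
}

#' Simulate a skin-temperature logger trace
#'
#' 10-minute grid over the whole study. Cold-treatment bats sit just above
#' ambient (torpid) with one evening arousal excursion to normothermia per
#' day; warm-treatment bats fluctuate inside the configured daytime band
#' with a few brief normothermic excursions. Gaussian logger noise is added
#' and readings are quantized to the 0.5 deg C logger grid; skin
#' temperature never falls below ambient.
#'
#' @param cfg a [sim_config()].
#' @param bat one row of the cohort data.frame.
#' @return temperature-series data.frame (`bat_id, deployment, timestamp,
#'   tsk_c, ta_c, included`).
#' @export
simulate_tsk <- function(cfg, bat) {
  set.seed(substream_seed(cfg$seed, paste0("tsk_", bat$bat_id)))
  nd <- total_days(cfg)
  per_day <- 24 * 60 / 10
  ts <- as.POSIXct(paste(cfg$day0_date, "00:00:00"), tz = "UTC") +
    seq(0, nd * per_day - 1) * 600
  ta <- unname(cfg$treatments[bat$treatment])
  hour <- (seq_along(ts) - 1) %% per_day * 10 / 60
  n_ar <- ceiling(cfg$arousal_len_min / 10)
  cold <- bat$treatment == names(cfg$treatments)[1]
  if (cold) {
    tsk <- rep(ta + cfg$torpid_offset_c, length(ts))
    ar <- hour >= cfg$arousal_hour & hour < cfg$arousal_hour + n_ar * 10 / 60
    tsk[ar] <- cfg$normothermic_c
  } else {
    mid <- mean(cfg$t25_band); amp <- diff(cfg$t25_band) / 2
    tsk <- mid + amp * sin(2 * pi * (hour - 6) / 24)
    # brief normothermic excursions at random clock slots, fixed per day
    for (d in seq_len(nd) - 1) {
      k <- rbinom(1, cfg$t25_arousals_per_day * 2, 0.5)
      if (k == 0) next
      at <- sample.int(per_day - n_ar, k)
      for (a in at) {
        idx <- d * per_day + a + seq_len(n_ar)
        tsk[idx] <- cfg$normothermic_c + 0.5
      }
    }
  }
  noise <- if (cfg$tsk_noise_sd > 0) rnorm(length(ts), 0, cfg$tsk_noise_sd)
           else 0
  tsk <- round((tsk + noise) / 0.5) * 0.5
  tsk <- pmax(tsk, round(ta / 0.5) * 0.5)
  data.frame(bat_id = bat$bat_id, deployment = 1L, timestamp = ts,
             tsk_c = tsk, ta_c = ta, included = TRUE)
}

#' Simulate latent transition days
#'
#' Draws of the day on which the latent maturation variable crosses each
#' free threshold, for one treatment and covariate profile:
#' `T_k(profile) - u - eps` with `u ~ N(0, sigma_u^2)` and
#' `eps ~ N(0, sigma_eps^2)`. The marginal distribution for transition `k`
#' is exactly `N(tau_k + delay_k + effects, sigma_u^2 + sigma_eps^2)`.
#'
#' @param truth a [sim_truth()].
#' @param treatment `"T10"` or `"T25"`.
#' @param n number of draws.
#' @param mass_c,delta_t_c centred covariate profile.
#' @param seed RNG seed.
#' @return matrix `n x length(truth$tau)`.
#' @export
simulate_transition_days <- function(truth, treatment, n, mass_c = 0,
                                     delta_t_c = 0, seed = 1L) {
  set.seed(substream_seed(seed, "transition_days"))
  alt <- treatment == "T10"
  thr <- truth$tau + (if (alt) truth$delay else 0) +
    truth$gamma_mass[treatment, ] * mass_c +
    truth$gamma_dt[treatment, ] * delta_t_c
  u <- rnorm(n, 0, truth$sigma_u)
  eps <- rnorm(n, 0, truth$sigma_eps)
  out <- outer(-(u + eps), thr, `+`)
  colnames(out) <- paste0("T[", seq_along(thr) + 1, "]")
  out
}

#' Simulate ordinal maturation examinations
#'
#' The generative twin of the model likelihood: for each bat a random shift
#' `u_i ~ N(0, sigma_u^2)` is drawn; at each examination day `t` a single
#' latent draw `t + u_i + eps` (with `eps ~ N(0, sigma_eps^2)`) is compared
#' to the effective thresholds (fixed day-10 first transition; later
#' transitions shifted by treatment delay and covariate effects) and the
#' emitted class is the number of thresholds crossed. With
#' `cfg$monotone = TRUE` (the default) classes are made non-decreasing over
#' a bat's exams (running maximum), reflecting the sequential biology of
#' spermatogenesis.
#'
#' @param cfg a [sim_config()].
#' @param bats cohort data.frame with assigned treatments.
#' @param covars data.frame `bat_id, day, mass_c, delta_t_c` (centred; `NA`
#'   treated as 0 at generation).
#' @return maturation observations data.frame `bat_id, day, cls`.
#' @export
simulate_maturation <- function(cfg, bats, covars) {
  set.seed(substream_seed(cfg$seed, "maturation"))
  tr <- cfg$truth
  u <- rnorm(nrow(bats), 0, tr$sigma_u)
  names(u) <- bats$bat_id
  out <- covars[c("bat_id", "day")]
  out <- out[order(out$bat_id, out$day), ]
  rows <- lapply(seq_len(nrow(out)), function(r) {
    b <- out$bat_id[r]
    i <- match(b, bats$bat_id)
    g <- bats$treatment[i]
    cr <- covars[covars$bat_id == b & covars$day == out$day[r], ][1, ]
    m <- if (is.na(cr$mass_c)) 0 else cr$mass_c
    dtv <- if (is.na(cr$delta_t_c)) 0 else cr$delta_t_c
    thr <- c(10, tr$tau + (if (g == "T10") tr$delay else 0) +
               tr$gamma_mass[g, ] * m + tr$gamma_dt[g, ] * dtv)
    lat <- out$day[r] + u[b] + rnorm(1, 0, tr$sigma_eps)
    sum(lat >= thr)
  })
  out$cls <- as.integer(unlist(rows))
  if (cfg$monotone) {
    out$cls <- unlist(lapply(split(out$cls, out$bat_id), cummax),
                      use.names = FALSE)
    # split() reorders by bat_id; out is already sorted that way
  }
  rownames(out) <- NULL
  out
}

#' Simulate a complete study and write its file set
#'
#' Generates cohort, daily masses and per-bat logger traces, runs the
#' thermoregulation pipeline to obtain examination-day covariates, draws
#' ordinal maturation observations from the transition-time model, and
#' writes `cohort.csv`, `temps.csv`, `masses.csv`, `obs.csv` and
#' `truth.json` (the generating parameters) to `outdir`.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created if needed); existing target
#'   files are an error.
#' @param config a [study_config()] used for the thermoregulation pipeline
#'   (exclusion windows, day 0).
#' @return invisibly, a list with the generated data frames and file paths.
#' @export
simulate_study <- function(cfg, outdir,
                           config = study_config(day0 = cfg$day0_date,
                                                 seed = cfg$seed)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outdir, c("cohort.csv", "temps.csv", "masses.csv",
                               "obs.csv", "truth.json"))
  names(paths) <- c("cohort", "temps", "masses", "obs", "truth")
  if (any(file.exists(paths))) {
    stop("output file(s) already exist in ", outdir, call. = FALSE)
  }
  ch <- simulate_cohort(cfg)
  temps <- do.call(rbind, lapply(seq_len(nrow(ch$bats)), function(i) {
    simulate_tsk(cfg, ch$bats[i, ])
  }))
  temps <- apply_exclusions(temps, config$exclusion_windows)
  thr <- per_individual_thresholds(ch$bats, ch$masses, config)
  events <- detect_torpor_events(temps, thr, config$min_run)
  dailies <- daily_summaries(temps, events, config)
  exam_days <- seq(0, total_days(cfg) - 2, by = cfg$exam_interval)
  obs0 <- expand.grid(bat_id = ch$bats$bat_id, day = exam_days,
                      stringsAsFactors = FALSE)
  mass <- ch$masses$mass_g[match(paste(obs0$bat_id, obs0$day),
                                 paste(ch$masses$bat_id, ch$masses$day))]
  dtv <- dailies$delta_t_c[match(paste(obs0$bat_id, obs0$day),
                                 paste(dailies$bat_id, dailies$day))]
  covars <- data.frame(bat_id = obs0$bat_id, day = obs0$day,
                       mass_c = mass - mean(mass, na.rm = TRUE),
                       delta_t_c = dtv - mean(dtv, na.rm = TRUE))
  obs <- simulate_maturation(cfg, ch$bats, covars)
  write.csv(ch$bats, paths["cohort"], row.names = FALSE)
  tw <- temps
  tw$timestamp <- format(tw$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(tw[c("bat_id", "timestamp", "tsk_c", "ta_c")], paths["temps"],
            row.names = FALSE)
  write.csv(ch$masses, paths["masses"], row.names = FALSE)
  write.csv(obs, paths["obs"], row.names = FALSE)
  write_truth(cfg$truth, paths["truth"])
  invisible(list(bats = ch$bats, masses = ch$masses, temps = temps,
                 events = events, dailies = dailies, obs = obs,
                 paths = paths))
}

#' Write or read generating parameters as JSON
#'
#' @param truth a [sim_truth()].
#' @param path JSON file path.
#' @return `read_truth()` returns a `sim_truth`; `write_truth()` the path,
#'   invisibly.
#' @export
write_truth <- function(truth, path) {
  x <- list(tau = truth$tau, delay = truth$delay,
            gamma_mass = list(T25 = unname(truth$gamma_mass["T25", ]),
                              T10 = unname(truth$gamma_mass["T10", ])),
            gamma_dt = list(T25 = unname(truth$gamma_dt["T25", ]),
                            T10 = unname(truth$gamma_dt["T10", ])),
            sigma_u = truth$sigma_u, sigma_eps = truth$sigma_eps)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_truth(tau = x$tau, delay = x$delay,
            gamma_mass = rbind(T25 = x$gamma_mass$T25, T10 = x$gamma_mass$T10),
            gamma_dt = rbind(T25 = x$gamma_dt$T25, T10 = x$gamma_dt$T10),
            sigma_u = x$sigma_u, sigma_eps = x$sigma_eps)
}
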