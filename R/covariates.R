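#' Assign treatments balanced on body condition
#'
#' Body condition index (BCI) is forearm length divided by capture mass
#' (mm/g, as conventionally scored in this study system). Bats are ranked by
#' BCI and consecutive pairs are split at random between the two treatments,
#' yielding matched BCI distributions. An odd cohort gets its last bat
#' assigned at random with a warning.
#'
#' @param bats cohort data.frame; `treatment` is overwritten.
#' @param seed RNG seed for the pair splits.
#' @param labels two treatment labels, first is the cold arm.
#' @return the cohort with `treatment` filled in.
#' @export
assign_treatments <- function(bats, seed = 1L, labels = c("T10", "T25")) {
  stopifnot(length(labels) == 2)
  if (!nrow(bats)) return(bats)
  set.seed(substream_seed(seed, "assign_treatments"))
  bci <- bats$forearm_mm / bats$capture_mass_g
  ord <- order(bci, decreasing = TRUE)
  n <- nrow(bats)
  trt <- character(n)
  i <- 1L
  while (i + 1L <= n) {
    flip <- runif(1) < 0.5
    trt[ord[i]] <- if (flip) labels[1] else labels[2]
    trt[ord[i + 1L]] <- if (flip) labels[2] else labels[1]
    i <- i + 2L
  }
  if (i == n) {
    warning("odd cohort size: last bat assigned at random")
    trt[ord[n]] <- sample(labels, 1)
  }
  bats$treatment <- trt
  bats
}

#' Build the per-examination covariate table
#'
#' Joins each ordinal maturation examination to the body mass and
#' thermoregulation effort (delta T) recorded on the examination day, then
#' centres both covariates on their pooled means over non-missing attached
#' values. A covariate absent on an exam day stays `NA` and is flagged
#' missing — it is imputed inside the model, never interpolated here.
#' Centering constants are stored as attributes `mass_center` and
#' `delta_t_center` so raw values can be recovered exactly.
#'
#' @param obs maturation observations (see [read_maturation_obs()]).
#' @param masses mass records.
#' @param dailies daily summaries from [daily_summaries()] (may be `NULL`:
#'   all delta T missing).
#' @param bats cohort data.frame with assigned treatments.
#' @return data.frame `bat_id, day, cls, treatment, group_id, mass_c,
#'   delta_t_c, mass_missing, delta_t_missing`, one row per observation.
#' @export
build_exam_table <- function(obs, masses, dailies, bats) {
  unknown <- setdiff(obs$bat_id, bats$bat_id)
  if (length(unknown)) {
    stop("observation(s) for unknown bat(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bi <- match(obs$bat_id, bats$bat_id)
  mass <- masses$mass_g[match(paste(obs$bat_id, obs$day),
                              paste(masses$bat_id, masses$day))]
  dtv <- if (is.null(dailies) || !nrow(dailies)) rep(NA_real_, nrow(obs))
         else dailies$delta_t_c[match(paste(obs$bat_id, obs$day),
                                      paste(dailies$bat_id, dailies$day))]
  mass_center <- if (all(is.na(mass))) 0 else mean(mass, na.rm = TRUE)
  dt_center <- if (all(is.na(dtv))) 0 else mean(dtv, na.rm = TRUE)
  out <- data.frame(
    bat_id = obs$bat_id, day = obs$day, cls = obs$cls,
    treatment = bats$treatment[bi], group_id = bats$group_id[bi],
    mass_c = mass - mass_center, delta_t_c = dtv - dt_center,
    mass_missing = is.na(mass), delta_t_missing = is.na(dtv)
  )
  attr(out, "mass_center") <- mass_center
  attr(out, "delta_t_center") <- dt_center
  out
}

#' Scale days since capture to years
#'
#' Division by 365 used internally by the sampler when year-scaling is
#' enabled; every reported quantity is converted back to days.
#'
#' @param day day(s) since capture, `>= 0`.
#' @return `day / 365`.
#' @export
scale_time <- function(day) {
  day / 365
}
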