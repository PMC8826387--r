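#' Study configuration
#'
#' Collects the fixed conventions of a study: treatment ambient temperatures,
#' daily clock windows during which logger readings are excluded (handling,
#' feeding, flight), the minimum run length that defines a torpor bout, the
#' day-numbering origin, and MCMC sampler settings. Day of capture is day 0;
#' the temperature treatment starts on day 10, so "experiment day" is
#' `day - 10`.
#'
#' @param treatments named numeric vector of ambient temperatures in deg C,
#'   names are the treatment labels (default `c(T10 = 10, T25 = 25)`).
#' @param exclusion_windows list of length-2 character vectors `c("HH:MM",
#'   "HH:MM")`, half-open daily clock intervals whose readings are masked out.
#' @param min_run minimum number of consecutive sub-threshold readings that
#'   constitutes a torpor bout (default 3).
#' @param min_daily_readings minimum number of included readings for a day to
#'   be summarised (default 6, i.e. one hour of coverage).
#' @param day0 `Date` (or "YYYY-MM-DD") of capture; if `NULL`, taken per
#'   dataset as the date of the earliest reading.
#' @param daily_mass_threshold logical; if `TRUE`, torpor thresholds are
#'   recomputed per day from that day's mass rather than once per individual
#'   from the mean mass.
#' @param chains,iter,burnin,thin default MCMC settings (3 chains, 50000
#'   iterations, 20000 burn-in, thinning by 3).
#' @param seed root RNG seed.
#' @return an object of class `study_config` (a list).
#' @export
study_config <- function(treatments = c(T10 = 10, T25 = 25),
                         exclusion_windows = list(c("18:00", "19:00")),
                         min_run = 3L,
                         min_daily_readings = 6L,
                         day0 = NULL,
                         daily_mass_threshold = FALSE,
                         chains = 3L, iter = 50000L, burnin = 20000L,
                         thin = 3L, seed = 1L) {
  stopifnot(is.numeric(treatments), length(treatments) >= 1,
            !is.null(names(treatments)))
  if (min_run < 1) stop("min_run must be >= 1")
  if (chains < 2) stop("at least 2 chains are required for Rhat")
  if (!is.null(day0)) day0 <- as.Date(day0)
  structure(list(
    treatments = treatments,
    exclusion_windows = exclusion_windows,
    min_run = as.integer(min_run),
    min_daily_readings = as.integer(min_daily_readings),
    day0 = day0,
    daily_mass_threshold = isTRUE(daily_mass_threshold),
    chains = as.integer(chains), iter = as.integer(iter),
    burnin = as.integer(burnin), thin = as.integer(thin),
    seed = as.integer(seed)
  ), class = "study_config")
}

#' Read or write a study configuration (YAML or JSON)
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `read_study_config()` returns a `study_config`;
#'   `write_study_config()` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  tr <- unlist(raw$treatments)
  ex <- raw$exclusion_windows
  if (is.matrix(ex)) ex <- asplit(ex, 1)
  ex <- lapply(ex, function(w) as.character(unlist(w)))
  study_config(
    treatments = tr,
    exclusion_windows = ex,
    min_run = raw$min_run %||% 3L,
    min_daily_readings = raw$min_daily_readings %||% 6L,
    day0 = raw$day0,
    daily_mass_threshold = raw$daily_mass_threshold %||% FALSE,
    chains = raw$chains %||% 3L, iter = raw$iter %||% 50000L,
    burnin = raw$burnin %||% 20000L, thin = raw$thin %||% 3L,
    seed = raw$seed %||% 1L
  )
}

#' @rdname read_study_config
#' @param config a `study_config` object.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  x <- unclass(config)
  x$treatments <- as.list(config$treatments)
  x$day0 <- if (is.null(x$day0)) NULL else format(x$day0)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
}

#' Read a cohort table
#'
#' Per-individual metadata: ID, forearm length (mm), mass at capture (g),
#' treatment label and housing-group ID. Treatment labels must be drawn from
#' the configured set; `NA` treatment is allowed for a cohort that has not
#' been assigned yet (see [assign_treatments()]).
#'
#' @param path CSV with header columns `bat_id, forearm_mm, capture_mass_g,
#'   treatment, group_id`.
#' @param treatments allowed treatment labels.
#' @return data.frame with those five columns, one row per bat.
#' @export
read_cohort <- function(path, treatments = c("T10", "T25")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("bat_id", "forearm_mm", "capture_mass_g",
                      "treatment", "group_id"), "cohort")
  df$bat_id <- as.character(df$bat_id)
  df$group_id <- as.character(df$group_id)
  validate_cohort(df, treatments)
}

validate_cohort <- function(df, treatments = c("T10", "T25")) {
  if (anyDuplicated(df$bat_id)) {
    stop("cohort: duplicated bat_id: ",
         paste(unique(df$bat_id[duplicated(df$bat_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(df$forearm_mm) & df$forearm_mm <= 0)) {
    stop("cohort: forearm_mm must be > 0", call. = FALSE)
  }
  if (any(!is.na(df$capture_mass_g) & df$capture_mass_g <= 0)) {
    stop("cohort: capture_mass_g must be > 0", call. = FALSE)
  }
  bad <- !is.na(df$treatment) & df$treatment != "" &
    !(df$treatment %in% treatments)
  if (any(bad)) {
    stop("cohort: unknown treatment token(s): ",
         paste(unique(df$treatment[bad]), collapse = ", "), call. = FALSE)
  }
  df$treatment[!is.na(df$treatment) & df$treatment == ""] <- NA_character_
  df
}

#' Read skin-temperature logger series
#'
#' Long-format logger export: one row per reading with skin temperature
#' (`tsk_c`) and ambient temperature (`ta_c`). Readings are grouped per bat;
#' within a bat, a gap of more than one sampling interval starts a new
#' logger deployment (loggers detach and are re-glued), so downstream run
#' detection never bridges a gap. The inclusion mask starts all-`TRUE`.
#' Skin temperatures are expected on a 0.5 deg C grid; off-grid values are
#' kept with a warning.
#'
#' @param path CSV with header columns `bat_id, timestamp, tsk_c, ta_c`;
#'   timestamps ISO-8601, interpreted in UTC.
#' @param interval_min sampling interval in minutes (default 10).
#' @return data.frame `bat_id, deployment, timestamp (POSIXct), tsk_c, ta_c,
#'   included`, ordered by bat and time.
#' @export
read_temp_series <- function(path, interval_min = 10) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("bat_id", "timestamp", "tsk_c", "ta_c"), "temp series")
  df$bat_id <- as.character(df$bat_id)
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%d"))
  if (anyNA(ts)) stop("temp series: unparseable timestamp(s)", call. = FALSE)
  df$timestamp <- ts
  out <- do.call(rbind, lapply(split(df, df$bat_id), function(d) {
    d <- d[order(d$timestamp), , drop = FALSE]
    dt <- diff(as.numeric(d$timestamp))
    if (any(dt <= 0)) {
      stop("temp series: non-increasing timestamps for bat ", d$bat_id[1],
           call. = FALSE)
    }
    # gap > one sampling interval (with slack for clock jitter) splits
    d$deployment <- cumsum(c(1L, as.integer(dt > interval_min * 60 * 1.5)))
    d
  }))
  rownames(out) <- NULL
  off <- abs(out$tsk_c / 0.5 - round(out$tsk_c / 0.5)) > 1e-6
  if (any(off)) {
    warning(sum(off), " tsk_c value(s) not on the 0.5 deg C grid; kept as-is")
  }
  out$included <- TRUE
  out[c("bat_id", "deployment", "timestamp", "tsk_c", "ta_c", "included")]
}

#' Read daily body-mass records
#'
#' @param path CSV with header columns `bat_id, day, mass_g` (`day` is an
#'   integer day since capture; one record per bat and day).
#' @return data.frame with those columns.
#' @export
read_mass_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("bat_id", "day", "mass_g"), "mass records")
  df$bat_id <- as.character(df$bat_id)
  df$day <- as.integer(df$day)
  if (any(df$mass_g <= 0, na.rm = TRUE)) {
    stop("mass records: mass_g must be > 0", call. = FALSE)
  }
  if (anyDuplicated(df[c("bat_id", "day")])) {
    stop("mass records: more than one record per bat and day", call. = FALSE)
  }
  df
}

#' Read ordinal maturation examinations
#'
#' Each row is one visual staging of a bat on a given day since capture,
#' with class in 0..4 (0 = no visible testicular growth, 2 = maximal testes,
#' 4 = regressed testes with filled epididymides). Examinations are expected
#' roughly every 10 days; larger spacing only triggers a warning.
#'
#' @param path CSV with header columns `bat_id, day, cls`.
#' @param n_classes number of ordinal classes (default 5, i.e. 0..4).
#' @return data.frame with those columns.
#' @export
read_maturation_obs <- function(path, n_classes = 5L) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("bat_id", "day", "cls"), "maturation obs")
  df$bat_id <- as.character(df$bat_id)
  df$day <- as.integer(df$day)
  df$cls <- as.integer(df$cls)
  if (any(df$cls < 0 | df$cls >= n_classes)) {
    stop("maturation obs: cls outside 0..", n_classes - 1, call. = FALSE)
  }
  gaps <- unlist(lapply(split(df$day, df$bat_id),
                        function(d) diff(sort(unique(d)))))
  if (length(gaps) && any(gaps > 20)) {
    warning("examination spacing exceeds 20 days for some bats")
  }
  df
}

#' Write a posterior summary table
#'
#' One row per reported parameter with posterior mean, sd, 2.5/50/97.5
#' percentiles, the Gelman-Rubin statistic and the significance flag (95%
#' credible interval excludes 0).
#'
#' @param summary a data.frame as returned by [summary.maturation_fit()], or
#'   the fit itself.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_posterior_summary <- function(summary, path) {
  if (inherits(summary, "maturation_fit")) summary <- summary(summary)
  check_columns(summary, c("parameter", "mean", "sd", "q2.5", "q50",
                           "q97.5", "rhat", "significant"),
                "posterior summary")
  write.csv(summary, path, row.names = FALSE)
  invisible(path)
}

#' Write torpor events or daily summaries to CSV
#'
#' Thin writers for the outputs of [detect_torpor_events()] (timestamps
#' serialised as ISO-8601 UTC) and [daily_summaries()].
#'
#' @param events,dailies data.frames produced by the pipeline.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_torpor_events <- function(events, path) {
  ev <- events
  ev$start <- format(ev$start, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  ev$end <- format(ev$end, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(ev, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_torpor_events
#' @export
write_daily_summaries <- function(dailies, path) {
  write.csv(dailies, path, row.names = FALSE)
  invisible(path)
}
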