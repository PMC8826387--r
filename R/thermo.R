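#' Individual torpor-onset threshold
#'
#' Skin-temperature cutoff below which a reading counts as torpid, as a
#' linear function of body mass and ambient temperature:
#' `0.041 * mass_g + 0.04 * ta_c + 31.083` (deg C). The right-hand side
#' already carries the 1-SE buffer of the underlying allometric regression
#' and is used directly as the cutoff.
#'
#' @param mass_g body mass in grams (> 0); vectorised.
#' @param ta_c ambient temperature in deg C; vectorised.
#' @return threshold in deg C.
#' @examples
#' torpor_onset_threshold(11.1, 25) # 32.5381
#' @export
torpor_onset_threshold <- function(mass_g, ta_c) {
  if (any(!is.finite(mass_g)) || any(mass_g <= 0)) {
    stop("mass_g must be finite and > 0", call. = FALSE)
  }
  0.041 * mass_g + 0.04 * ta_c + 31.083
}

#' Per-individual torpor thresholds
#'
#' One threshold per bat from [torpor_onset_threshold()], using the bat's
#' mean body mass over its records (a single stable threshold per
#' deployment) and the ambient temperature of its treatment. With
#' `config$daily_mass_threshold = TRUE` a per-day threshold table is
#' returned instead.
#'
#' @param bats cohort data.frame (see [read_cohort()]); every bat must have
#'   an assigned treatment.
#' @param masses mass records data.frame (see [read_mass_records()]).
#' @param config a [study_config()].
#' @return named numeric vector `bat_id -> deg C`, or (daily mode) a
#'   data.frame `bat_id, day, threshold_c`.
#' @export
per_individual_thresholds <- function(bats, masses, config = study_config()) {
  ta <- config$treatments[bats$treatment]
  if (anyNA(ta)) {
    stop("unassigned or unknown treatment for bat(s): ",
         paste(bats$bat_id[is.na(ta)], collapse = ", "), call. = FALSE)
  }
  no_mass <- setdiff(bats$bat_id, masses$bat_id)
  if (length(no_mass)) {
    stop("no mass record for bat(s): ", paste(no_mass, collapse = ", "),
         call. = FALSE)
  }
  if (config$daily_mass_threshold) {
    m <- masses[masses$bat_id %in% bats$bat_id, ]
    m$threshold_c <- torpor_onset_threshold(
      m$mass_g, ta[match(m$bat_id, bats$bat_id)])
    return(m[c("bat_id", "day", "threshold_c")])
  }
  mean_mass <- vapply(split(masses$mass_g, masses$bat_id), mean, 0)
  mm <- mean_mass[bats$bat_id]
  out <- torpor_onset_threshold(mm, ta)
  names(out) <- bats$bat_id
  out
}

parse_clock_min <- function(x) {
  p <- strsplit(x, ":", fixed = TRUE)[[1]]
  as.numeric(p[1]) * 60 + as.numeric(p[2])
}

#' Mask readings inside daily exclusion windows
#'
#' Readings taken while animals were out of their cage (feeding, weighing,
#' flight) carry no thermoregulation information; they are masked out, never
#' deleted. Windows are half-open clock intervals `[start, end)` applied
#' every day; a window with `start > end` wraps midnight; overlapping
#' windows are merged silently.
#'
#' @param series temperature series data.frame (see [read_temp_series()]).
#' @param windows list of `c("HH:MM", "HH:MM")` character pairs.
#' @return the series with `included` set to `FALSE` inside the windows.
#' @export
apply_exclusions <- function(series, windows) {
  if (!length(windows)) return(series)
  lt <- as.POSIXlt(series$timestamp, tz = "UTC")
  clock_min <- lt$hour * 60 + lt$min + lt$sec / 60
  excl <- rep(FALSE, nrow(series))
  for (w in windows) {
    a <- parse_clock_min(w[1]); b <- parse_clock_min(w[2])
    excl <- excl | if (a <= b) clock_min >= a & clock_min < b
                   else clock_min >= a | clock_min < b
  }
  series$included <- series$included & !excl
  series
}

#' Detect torpor bouts
#'
#' A torpor bout is a maximal run of at least `min_run` consecutive included
#' readings with skin temperature strictly below the individual threshold.
#' Runs never bridge excluded readings or logger-deployment gaps (no
#' information while the animal is handled or the logger is off); bout
#' duration is `n_readings` sampling intervals, so an isolated reading
#' contributes exactly one interval.
#'
#' @param series temperature series data.frame.
#' @param threshold scalar threshold in deg C, or a named vector
#'   `bat_id -> deg C` as from [per_individual_thresholds()].
#' @param min_run minimum run length (default 3).
#' @param interval_min sampling interval in minutes (default 10).
#' @return data.frame `bat_id, start, end, n_readings, duration_h,
#'   min_tsk_c`, events sorted by bat and start time; zero rows if none.
#' @export
detect_torpor_events <- function(series, threshold, min_run = 3L,
                                 interval_min = 10) {
  stopifnot(min_run >= 1)
  empty <- data.frame(bat_id = character(), start = as.POSIXct(character()),
                      end = as.POSIXct(character()),
                      n_readings = integer(), duration_h = numeric(),
                      min_tsk_c = numeric())
  if (!nrow(series)) return(empty)
  if (is.null(series$deployment)) series$deployment <- 1L
  key <- paste(series$bat_id, series$deployment, sep = "\r")
  parts <- lapply(split(series, key), function(d) {
    thr <- if (length(threshold) == 1L && is.null(names(threshold))) {
      threshold
    } else {
      threshold[[d$bat_id[1]]]
    }
    if (is.null(thr) || is.na(thr)) {
      stop("no threshold for bat ", d$bat_id[1], call. = FALSE)
    }
    d <- d[order(d$timestamp), , drop = FALSE]
    torpid <- d$included & d$tsk_c < thr
    r <- rle(torpid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_run
    if (!any(keep)) return(NULL)
    data.frame(
      bat_id = d$bat_id[1],
      start = d$timestamp[starts[keep]],
      end = d$timestamp[ends[keep]],
      n_readings = r$lengths[keep],
      duration_h = r$lengths[keep] * interval_min / 60,
      min_tsk_c = vapply(which(keep), function(i) {
        min(d$tsk_c[starts[i]:ends[i]])
      }, 0)
    )
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts)) return(empty)
  out <- do.call(rbind, parts)
  out <- out[order(out$bat_id, out$start), ]
  rownames(out) <- NULL
  out
}

day_index <- function(timestamp, day0) {
  floor(as.numeric(difftime(timestamp, as.POSIXct(paste(day0, "00:00:00"),
                                                  tz = "UTC"),
                            units = "days")))
}

#' Daily thermoregulation summaries
#'
#' One row per bat and calendar day (midnight boundaries; days numbered from
#' capture, day 0): mean skin temperature, thermoregulation effort
#' `delta_t_c = mean(tsk_c - ta_c)` over included readings (signed, not
#' clamped), the number of torpor bouts starting that day and their mean
#' duration. Days with fewer included readings than
#' `config$min_daily_readings` are dropped; days with none are dropped with
#' a message.
#'
#' @param series temperature series data.frame (after [apply_exclusions()]).
#' @param events torpor events computed on the same series.
#' @param config a [study_config()]; supplies `day0` (defaults to the date
#'   of the earliest reading) and the minimum reading count.
#' @return data.frame `bat_id, day, mean_tsk_c, delta_t_c, n_torpor_events,
#'   mean_event_duration_h, n_included_readings`.
#' @export
daily_summaries <- function(series, events, config = study_config()) {
  day0 <- config$day0 %||% as.Date(min(series$timestamp))
  series$day <- day_index(series$timestamp, day0)
  inc <- series[series$included, , drop = FALSE]
  n_all <- table(paste(series$bat_id, series$day))
  n_inc <- table(paste(inc$bat_id, inc$day))
  silent_days <- setdiff(names(n_all), names(n_inc))
  if (length(silent_days)) {
    message(length(silent_days),
            " bat-day(s) with zero included readings omitted")
  }
  if (nrow(events)) {
    events$day <- day_index(events$start, day0)
    ev_key <- paste(events$bat_id, events$day)
  } else {
    ev_key <- character()
  }
  parts <- lapply(split(inc, paste(inc$bat_id, inc$day)), function(d) {
    if (nrow(d) < config$min_daily_readings) return(NULL)
    k <- paste(d$bat_id[1], d$day[1])
    ev <- if (length(ev_key)) events[ev_key == k, , drop = FALSE]
          else events[0, , drop = FALSE]
    data.frame(
      bat_id = d$bat_id[1], day = d$day[1],
      mean_tsk_c = mean(d$tsk_c),
      delta_t_c = mean(d$tsk_c - d$ta_c),
      n_torpor_events = nrow(ev),
      mean_event_duration_h = if (nrow(ev)) mean(ev$duration_h) else NA_real_,
      n_included_readings = nrow(d)
    )
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts)) {
    return(data.frame(bat_id = character(), day = integer(),
                      mean_tsk_c = numeric(), delta_t_c = numeric(),
                      n_torpor_events = integer(),
                      mean_event_duration_h = numeric(),
                      n_included_readings = integer()))
  }
  out <- do.call(rbind, parts)
  out <- out[order(out$bat_id, out$day), ]
  rownames(out) <- NULL
  out
}
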