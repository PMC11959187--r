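#' Acclimation-window mean temperature
#'
#' Mean temperature over the half-open window `[trial_time - days,
#' trial_time)`: all information up to, but not including, the trial start.
#' Coverage is the number of present hours divided by the number expected
#' (`24 * days` for an hourly series); a mean at coverage below the floor is
#' refused rather than silently returned.
#'
#' @param series an hourly [temp_series] (completed, i.e. gap-filled, for
#'   trustworthy coverage).
#' @param trial_time POSIXct trial start.
#' @param days window length in whole days (>= 1).
#' @param coverage_floor minimum acceptable coverage (default 0.8).
#' @return A list: `mean` (degC), `coverage` in `[0,1]`,
#'   `fraction_recorded`.
#' @export
window_mean <- function(series, trial_time, days, coverage_floor = 0.8) {
  if (days < 1) stop("`days` must be >= 1", call. = FALSE)
  w <- restrict_window(series, trial_time - days * 86400, trial_time)
  expected <- days * 24
  coverage <- nrow(w) / expected
  if (nrow(w) == 0 || coverage < coverage_floor) {
    stop(sprintf(
      "site '%s': %d-day window before %s has coverage %.2f (< %.2f)",
      site_id(series), as.integer(days), format(trial_time), coverage,
      coverage_floor), call. = FALSE)
  }
  list(mean = mean(w$temp_c), coverage = min(coverage, 1),
       fraction_recorded = mean(w$source == "recorded"))
}

#' Diel temperature fluctuation statistics
#'
#' For each civil day in the window with at least 18 of 24 hours present,
#' the diel fluctuation is that day's maximum minus minimum. Days with fewer
#' hours are skipped so gaps cannot deflate (or inflate) the range.
#'
#' @param series an hourly [temp_series].
#' @param start,end POSIXct window bounds (half-open).
#' @param min_hours minimum hours per day for the day to qualify
#'   (default 18).
#' @return A list: `mean_diel`, `max_diel` (degC), `n_days` used.
#' @export
diel_stats <- function(series, start, end, min_hours = 18) {
  w <- restrict_window(series, start, end)
  if (nrow(w) == 0) stop("empty window", call. = FALSE)
  day <- format(w$datetime, "%Y-%m-%d")
  spl <- split(w$temp_c, day)
  fluct <- vapply(spl, function(v) {
    if (length(v) < min_hours) NA_real_ else max(v) - min(v)
  }, numeric(1))
  fluct <- fluct[!is.na(fluct)]
  if (!length(fluct)) {
    stop(sprintf("no day in window has >= %d hours of data", min_hours),
         call. = FALSE)
  }
  list(mean_diel = mean(fluct), max_diel = max(fluct), n_days = length(fluct))
}

#' Seasonal maximum temperature
#'
#' Maximum value in the window and the time it occurred (recorded and
#' imputed points both count); ties go to the earliest occurrence.
#'
#' @inheritParams diel_stats
#' @return A list: `max` (degC), `datetime`, `source` of the maximal point.
#' @export
seasonal_max <- function(series, start, end) {
  w <- restrict_window(series, start, end)
  if (nrow(w) == 0) stop("empty window", call. = FALSE)
  i <- which.max(w$temp_c)  # first index at ties
  list(max = w$temp_c[i], datetime = w$datetime[i], source = w$source[i])
}

#' Mean daytime temperature
#'
#' Mean over points whose local clock time falls in the half-open daily
#' interval `[day_hours[1], day_hours[2])` (default 09:00--19:00).
#'
#' @inheritParams diel_stats
#' @param day_hours numeric length-2 vector of clock hours.
#' @return Mean temperature (degC).
#' @export
daytime_mean <- function(series, start, end, day_hours = c(9, 19)) {
  w <- restrict_window(series, start, end)
  if (nrow(w) == 0) stop("empty window", call. = FALSE)
  lt <- as.POSIXlt(w$datetime)
  hod <- lt$hour + lt$min / 60
  keep <- hod >= day_hours[1] & hod < day_hours[2]
  if (!any(keep)) stop("no points in daytime interval", call. = FALSE)
  mean(w$temp_c[keep])
}

#' Trial warming-rate quality assurance
#'
#' Least-squares slope of logged ramp temperature on elapsed hours, with a
#' QA flag when the realized rate falls outside the acceptance band
#' (default 3.89--4.09 degC/h around the nominal 4 degC/h).
#'
#' @param trial a `trial_record` from [simulate_ramp()], or a [temp_series]
#'   of ramp readings.
#' @param band numeric length-2 acceptance band (degC per hour).
#' @return A list: `rate` (degC/h), `resid_sd` (degC), `qa_pass`, `n`.
#' @export
ramp_rate <- function(trial, band = c(3.89, 4.09)) {
  ramp <- if (inherits(trial, "trial_record")) trial$ramp else trial
  if (nrow(ramp) < 10) stop("need >= 10 ramp points", call. = FALSE)
  tnum <- as.numeric(ramp$datetime)
  if (any(diff(tnum) <= 0)) stop("non-monotone ramp timestamps", call. = FALSE)
  hours <- (tnum - tnum[1]) / 3600
  fit <- stats::lm.fit(cbind(1, hours), ramp$temp_c)
  rate <- fit$coefficients[2]
  resid_sd <- if (nrow(ramp) > 2) {
    sqrt(sum(fit$residuals^2) / (nrow(ramp) - 2))
  } else 0
  list(rate = unname(rate), resid_sd = resid_sd,
       qa_pass = rate >= band[1] && rate <= band[2], n = nrow(ramp))
}

#' Acclimation table: window means for every site and window
#'
#' One row per site and candidate window, giving the window mean, its
#' coverage and the fraction of in-window hours that were recorded rather
#' than imputed.
#'
#' @param streams named list of completed hourly [temp_series], one per site.
#' @param trial_times named POSIXct vector of trial starts per site.
#' @param windows integer vector of window lengths in days
#'   (default `c(1, 4, 8, 14, 30, 40)`).
#' @param coverage_floor per-window coverage floor passed to
#'   [window_mean()].
#' @return A data frame with columns `site_id`, `window_days`, `mean_temp`,
#'   `coverage`, `fraction_recorded`.
#' @export
acclimation_table <- function(streams, trial_times,
                              windows = c(1, 4, 8, 14, 30, 40),
                              coverage_floor = 0.8) {
  rows <- list()
  for (sid in names(streams)) {
    if (!(sid %in% names(trial_times)) || is.na(trial_times[[sid]])) {
      stop("no trial time for site ", sid, call. = FALSE)
    }
    tt <- trial_times[[sid]]
    for (w in windows) {
      wm <- window_mean(streams[[sid]], tt, w, coverage_floor)
      rows[[length(rows) + 1]] <- data.frame(
        site_id = sid, window_days = w, mean_temp = wm$mean,
        coverage = wm$coverage, fraction_recorded = wm$fraction_recorded)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-site thermal regime summary
#'
#' Season mean, maximum (with its time), range, diel fluctuation statistics,
#' daytime mean and hours above each threshold for one site's completed
#' series.
#'
#' @param series an hourly [temp_series].
#' @param season POSIXct length-2 analysis window.
#' @param thresholds temperatures (degC) for exceedance counts.
#' @param day_hours daytime clock-hour interval.
#' @return A one-row data frame.
#' @export
thermal_regime_summary <- function(series, season = default_season(),
                                   thresholds = c(20, 22.5),
                                   day_hours = c(9, 19)) {
  w <- restrict_window(series, season[1], season[2])
  if (nrow(w) == 0) stop("empty season window", call. = FALSE)
  sm <- seasonal_max(series, season[1], season[2])
  ds <- diel_stats(series, season[1], season[2])
  out <- data.frame(
    site_id = site_id(series),
    season_mean = mean(w$temp_c),
    season_max = sm$max,
    season_max_time = sm$datetime,
    season_range = max(w$temp_c) - min(w$temp_c),
    mean_diel = ds$mean_diel,
    max_diel = ds$max_diel,
    mean_daytime = daytime_mean(series, season[1], season[2], day_hours),
    fraction_recorded = mean(w$source == "recorded"))
  for (th in thresholds) {
    out[[sprintf("hours_above_%g", th)]] <- sum(w$temp_c > th)
  }
  out
}
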