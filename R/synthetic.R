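#' Synthetic multi-site CTmax study generator
#'
#' The generator produces data with the statistical structure the analysis
#' assumes: hourly air temperature as annual sinusoid + diel sinusoid + AR(1)
#' weather noise; stream temperature as a lagged linear or logistic transfer
#' of air plus AR(1) noise; per-fish CTmax as a linear acclimation effect
#' plus a small nonlinear body-size bump, a Gaussian site random intercept
#' and Gaussian residual; and trial warming ramps at a nominal 4 degC/h with
#' realistic rate and measurement jitter. All randomness flows from one
#' explicit integer seed per call; the caller's RNG state is untouched.
#'
#' @name synthetic
NULL

# Run expr under set.seed(seed) without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Site scenario for the synthetic generator
#'
#' Bundles the ground truth for one site: the air-temperature climate, the
#' air-to-stream transfer model (an [air_water_model] built with
#' [awm_linear()] or [awm_logistic()]), its lag, and the stream noise level.
#' Regimes label broad hydrological classes: groundwater-buffered streams
#' (damped, small seasonal range), surface-runoff streams, lake-fed creeks
#' (warm summer peaks), and urban streams (flashy, near-linear response).
#'
#' @param site_id site label.
#' @param regime one of `"groundwater"`, `"surface"`, `"lake_fed"`,
#'   `"urban"`.
#' @param air_params named list: `mean` (annual mean, degC), `seasonal_amp`
#'   (annual sinusoid amplitude, degC), `diel_amp` (diel amplitude, degC),
#'   `ar1` (hourly AR(1) coefficient in `[0,1)`), `noise_sd` (AR(1)
#'   innovation sd, degC).
#' @param transfer_truth the true [air_water_model]; its `lag` slot is the
#'   true lag in hours.
#' @param stream_noise_sd AR(1) innovation sd of stream noise (degC).
#' @param stream_ar1 hourly AR(1) coefficient of stream noise.
#' @return An object of class `site_scenario`.
#' @export
site_scenario <- function(site_id, regime = "surface",
                          air_params = list(mean = 7, seasonal_amp = 14,
                                            diel_amp = 4, ar1 = 0.9835,
                                            noise_sd = 0.63),
                          transfer_truth = awm_logistic(22, 0.18, 10, lag = 6),
                          stream_noise_sd = 0.15,
                          stream_ar1 = 0.8) {
  stopifnot(regime %in% c("groundwater", "surface", "lake_fed", "urban"),
            air_params$diel_amp >= 0,
            air_params$ar1 >= 0, air_params$ar1 < 1,
            stream_noise_sd >= 0,
            inherits(transfer_truth, "air_water_model"))
  structure(list(site_id = as.character(site_id), regime = regime,
                 air_params = air_params, transfer_truth = transfer_truth,
                 lag_truth = transfer_truth$lag,
                 stream_noise_sd = stream_noise_sd, stream_ar1 = stream_ar1),
            class = "site_scenario")
}

#' Population-level CTmax truth
#'
#' The generative analogue of the fitted CTmax model:
#' `CTmax_i = beta0 + beta_acc * acc_site + body_curve(FL_i) + u_site + e_i`
#' with `u_site ~ N(0, sigma_site^2)` and `e_i ~ N(0, sigma_resid^2)`.
#' Defaults place the acclimation slope at 0.23 degC per degC and partition
#' the variance so that, over 20 sites spanning roughly 9.1--18.6 degC of
#' 30-day acclimation, the marginal and conditional R-squared of the default
#' scenario sit near 0.66 and 0.87 (sigma defaults calibrated by simulation).
#'
#' @param beta0 intercept (degC).
#' @param beta_acc acclimation slope (degC CTmax per degC acclimation).
#' @param body_curve function mapping fork length (mm) to a CTmax offset
#'   (degC); default a small Gaussian bump peaking at 124 mm.
#' @param sigma_site sd of site random intercepts (degC).
#' @param sigma_resid residual sd (degC).
#' @return An object of class `population_truth`.
#' @export
population_truth <- function(beta0 = 25.8, beta_acc = 0.23,
                             body_curve = default_body_curve(),
                             sigma_site = 0.48, sigma_resid = 0.38) {
  stopifnot(sigma_site >= 0, sigma_resid > 0, is.function(body_curve))
  structure(list(beta0 = beta0, beta_acc = beta_acc, body_curve = body_curve,
                 sigma_site = sigma_site, sigma_resid = sigma_resid),
            class = "population_truth")
}

#' @rdname population_truth
#' @param amplitude,peak_mm,width_mm bump height (degC), location of the
#'   interior maximum (mm) and Gaussian width (mm).
#' @export
default_body_curve <- function(amplitude = 0.15, peak_mm = 124,
                               width_mm = 45) {
  force(amplitude); force(peak_mm); force(width_mm)
  function(fl) amplitude * exp(-0.5 * ((fl - peak_mm) / width_mm)^2)
}

#' Simulate hourly air temperature
#'
#' Annual sinusoid (peak around day-of-year 200) + diel sinusoid (peak at
#' 16:00 local) + AR(1) noise.
#'
#' @param scenario a [site_scenario].
#' @param start,end POSIXct bounds; hourly (or finer) points are generated on
#'   `[start, end]`.
#' @param step_hours step between points in hours; must divide 24 evenly.
#' @param seed integer seed.
#' @return A [temp_series] (source `recorded`).
#' @export
simulate_air <- function(scenario, start, end, step_hours = 1, seed = 1) {
  if (step_hours <= 0) stop("`step_hours` must be positive", call. = FALSE)
  if ((24 / step_hours) %% 1 != 0) {
    stop("`step_hours` must divide one day evenly", call. = FALSE)
  }
  if (!(start < end)) stop("`start` must precede `end`", call. = FALSE)
  times <- seq(from = start, to = end, by = step_hours * 3600)
  p <- scenario$air_params
  det <- air_deterministic(times, p)
  noise <- with_seed(seed, ar1_noise(length(times), p$ar1, p$noise_sd,
                                     step = step_hours))
  temp_series(times, det + noise, "recorded",
              site_id = paste0(scenario$site_id, "_air"))
}

air_deterministic <- function(times, p) {
  lt <- as.POSIXlt(times)
  doy <- lt$yday + (lt$hour + lt$min / 60) / 24
  hod <- lt$hour + lt$min / 60
  p$mean +
    p$seasonal_amp * cos(2 * pi * (doy - 200) / 365.25) +
    p$diel_amp * cos(2 * pi * (hod - 16) / 24)
}

# AR(1) noise with hourly coefficient phi; for sub-hourly steps phi is
# rescaled so the process has the same decorrelation time.
ar1_noise <- function(n, phi, sd_innov, step = 1) {
  if (n == 0 || sd_innov == 0) return(numeric(n))
  phi_s <- phi^step
  e <- stats::rnorm(n, 0, sd_innov * sqrt(step))
  if (phi_s == 0) return(e)
  as.numeric(stats::filter(e, phi_s, method = "recursive"))
}

#' Simulate stream temperature from simulated air
#'
#' Applies the scenario's true transfer model to the air series lagged by the
#' true lag, then adds AR(1) stream noise. Noise enters after the transfer,
#' so with zero noise the generating model is exactly recoverable from the
#' output. Output timestamps are the air timestamps shifted by the lag; all
#' points are flagged `recorded`.
#'
#' @param air [temp_series] from [simulate_air()], hourly.
#' @param scenario a [site_scenario].
#' @param seed integer seed.
#' @return A [temp_series].
#' @export
simulate_stream <- function(air, scenario, seed = 1) {
  lag <- scenario$lag_truth
  if (nrow(air) <= lag) {
    stop("air series shorter than the true lag", call. = FALSE)
  }
  vals <- transfer_eval(scenario$transfer_truth, air$temp_c)
  noise <- with_seed(seed, ar1_noise(length(vals), scenario$stream_ar1,
                                     scenario$stream_noise_sd))
  temp_series(air$datetime + lag * 3600, vals + noise, "recorded",
              site_id = scenario$site_id)
}

#' Simulate individual fish CTmax records
#'
#' Draws fork lengths uniformly over `length_range`, site random intercepts
#' `N(0, sigma_site^2)` and residuals `N(0, sigma_resid^2)`, and assembles
#' `CTmax = beta0 + beta_acc * acc + body_curve(FL) + u_site + e`. Mass is
#' derived from length by a cubic condition-factor relation (jittered) so
#' that length and mass are strongly correlated, as in real samples.
#'
#' @param truth a [population_truth].
#' @param site_acc_means named numeric vector: acclimation-window mean
#'   temperature (degC) per site.
#' @param n_per_site fish per site (recycled across sites).
#' @param length_range fork-length range (mm) for the uniform draw.
#' @param seed integer seed.
#' @param trial_times optional named POSIXct vector of trial start times per
#'   site (defaults to NA).
#' @param p_unrecovered probability a fish fails to recover after the trial
#'   (such fish are excluded from all fits downstream).
#' @return A data frame of class `fish_records` with columns `fish_id`,
#'   `site_id`, `trial_time`, `fork_length_mm`, `mass_g`, `ctmax`,
#'   `recovered`; the site intercepts used are kept in attribute
#'   `site_effects`.
#' @export
simulate_fish <- function(truth, site_acc_means, n_per_site = 19,
                          length_range = c(74, 289), seed = 1,
                          trial_times = NULL, p_unrecovered = 0) {
  if (!length(site_acc_means)) stop("empty site map", call. = FALSE)
  if (is.null(names(site_acc_means))) {
    names(site_acc_means) <- paste0("site", seq_along(site_acc_means))
  }
  stopifnot(all(n_per_site >= 1), length_range[1] > 0,
            length_range[2] >= length_range[1])
  sites <- names(site_acc_means)
  n_per_site <- rep_len(n_per_site, length(sites))
  with_seed(seed, {
    u <- stats::rnorm(length(sites), 0, truth$sigma_site)
    names(u) <- sites
    rows <- lapply(seq_along(sites), function(i) {
      n <- n_per_site[i]
      fl <- stats::runif(n, length_range[1], length_range[2])
      e <- stats::rnorm(n, 0, truth$sigma_resid)
      ct <- truth$beta0 + truth$beta_acc * site_acc_means[i] +
        truth$body_curve(fl) + u[i] + e
      mass <- 1.25e-5 * fl^3 * exp(stats::rnorm(n, 0, 0.08))
      data.frame(site_id = sites[i], fork_length_mm = fl, mass_g = mass,
                 ctmax = ct,
                 recovered = stats::runif(n) >= p_unrecovered,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$fish_id <- sprintf("fish%04d", seq_len(nrow(out)))
    tt <- if (is.null(trial_times)) as.POSIXct(NA) else trial_times[out$site_id]
    out$trial_time <- tt
    out <- out[, c("fish_id", "site_id", "trial_time", "fork_length_mm",
                   "mass_g", "ctmax", "recovered")]
    rownames(out) <- NULL
    attr(out, "site_effects") <- u
    class(out) <- c("fish_records", "data.frame")
    out
  })
}

#' Simulate a CTmax trial warming ramp
#'
#' Builds a temperature ramp from `start_temp` rising at `rate` (the realized
#' per-trial rate is `rate` plus `N(0, rate_jitter_sd)`), logged at `cadence`
#' seconds with `N(0, temp_jitter_sd)` measurement noise, and assigns each
#' fish the timestamp at which the logged ramp first reaches its CTmax
#' (loss of equilibrium, LOE). Fish whose CTmax is at or below the start
#' temperature are flagged `immediate_loe`.
#'
#' @param start_temp ramp start temperature (degC).
#' @param rate nominal warming rate (degC per hour), must be positive.
#' @param fish a `fish_records` data frame (only `fish_id` and `ctmax` are
#'   used).
#' @param cadence logging cadence in seconds (default 15).
#' @param seed integer seed.
#' @param rate_jitter_sd sd of the per-trial deviation of the realized
#'   warming rate (degC per hour).
#' @param temp_jitter_sd sd of per-reading measurement noise (degC).
#' @param start_time POSIXct timestamp of the first ramp reading.
#' @return A list of class `trial_record`: `ramp` (a [temp_series]), `loe`
#'   (data frame fish_id, ctmax, loe_time, immediate_loe), `rate_nominal`,
#'   `rate_true`, `start_temp`.
#' @export
simulate_ramp <- function(start_temp, rate = 4, fish, cadence = 15, seed = 1,
                          rate_jitter_sd = 0.04, temp_jitter_sd = 0.05,
                          start_time = as.POSIXct("2021-07-01 12:00:00",
                                                  tz = "UTC")) {
  if (rate <= 0) stop("`rate` must be positive", call. = FALSE)
  with_seed(seed, {
    rate_true <- rate + stats::rnorm(1, 0, rate_jitter_sd)
    dur_h <- (max(fish$ctmax) - start_temp) / rate_true + 0.25
    dur_h <- max(dur_h, 0.25)
    tsec <- seq(0, ceiling(dur_h * 3600), by = cadence)
    temps <- start_temp + rate_true * tsec / 3600 +
      stats::rnorm(length(tsec), 0, temp_jitter_sd)
    ramp <- temp_series(start_time + tsec, temps, "recorded",
                        site_id = fish$site_id[1] %||% "trial")
    loe_idx <- vapply(fish$ctmax, function(ct) {
      hit <- which(temps >= ct)
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
    loe <- data.frame(fish_id = fish$fish_id, ctmax = fish$ctmax,
                      loe_time = start_time + tsec[loe_idx],
                      immediate_loe = fish$ctmax <= start_temp)
    structure(list(ramp = ramp, loe = loe, rate_nominal = rate,
                   rate_true = rate_true, start_temp = start_temp),
              class = "trial_record")
  })
}

#' Mask gaps into a temperature series
#'
#' Emulates heterogeneous logger deployments by removing points: whole (or
#' partial) outage intervals and/or a random fraction of all points.
#' Surviving points are never altered.
#'
#' @param series a [temp_series].
#' @param intervals optional data frame with POSIXct `start`, `end` and
#'   optional `fraction` (default 1) columns; within each half-open interval
#'   that fraction of points is removed at random (1 = full outage).
#' @param fraction overall random-masking fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return The masked [temp_series], with a gap inventory (data frame of
#'   removed spans) in attribute `gap_inventory`.
#' @export
mask_gaps <- function(series, intervals = NULL, fraction = 0, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  drop <- rep(FALSE, nrow(series))
  with_seed(seed, {
    if (!is.null(intervals)) {
      for (i in seq_len(nrow(intervals))) {
        frac_i <- if ("fraction" %in% names(intervals))
          intervals$fraction[i] else 1
        stopifnot(frac_i >= 0, frac_i <= 1)
        inside <- which(series$datetime >= intervals$start[i] &
                          series$datetime < intervals$end[i])
        if (frac_i >= 1) drop[inside] <- TRUE
        else if (frac_i > 0 && length(inside)) {
          drop[sample(inside, floor(frac_i * length(inside)))] <- TRUE
        }
      }
    }
    if (fraction > 0) {
      keep_idx <- which(!drop)
      drop[sample(keep_idx, floor(fraction * length(keep_idx)))] <- TRUE
    }
  })
  if (all(drop)) stop("gap pattern would remove all points", call. = FALSE)
  out <- ts_rebuild(as.data.frame(series)[!drop, , drop = FALSE],
                    site_id(series))
  removed <- series$datetime[drop]
  inv <- if (length(removed)) {
    brk <- c(0, which(diff(as.numeric(removed)) > 3600 * 1.5), length(removed))
    data.frame(start = removed[utils::head(brk, -1) + 1],
               end = removed[brk[-1]],
               n_points = diff(brk))
  } else data.frame(start = as.POSIXct(character()),
                    end = as.POSIXct(character()), n_points = integer())
  attr(out, "gap_inventory") <- inv
  out
}

#' Default 20-site study scenarios
#'
#' A fixed roster of 20 sites mirroring the composition of a southern/central
#' Ontario brook-trout study: mostly logistic air-water transfer (18 sites,
#' spanning strongly groundwater-buffered to warm lake-fed regimes) with two
#' near-linear urban streams; true lags between 2 and 24 h; cooler northern
#' climates for a minority of sites. Deterministic (no RNG): the roster is
#' part of the study conditions.
#'
#' @param n_sites number of sites (default 20).
#' @return A named list of [site_scenario] objects.
#' @export
default_scenarios <- function(n_sites = 20) {
  regimes <- rep(c("groundwater", "surface", "lake_fed", "urban"),
                 times = c(6, 7, 5, 2))
  regimes <- rep_len(regimes, n_sites)
  lags <- rep_len(c(6, 12, 3, 24, 9, 18, 4, 15, 2, 21), n_sites)
  scens <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    reg <- regimes[i]
    # deterministic within-regime spread so no two sites are identical
    j <- (i - 1) %% 5
    transfer <- switch(reg,
      groundwater = awm_logistic(L = 13 + 0.8 * j, k = 0.10 + 0.01 * j,
                                 x0 = 9 + 0.5 * j, lag = lags[i]),
      surface = awm_logistic(L = 21 + 0.7 * j, k = 0.16 + 0.015 * j,
                             x0 = 10 + 0.4 * j, lag = lags[i]),
      lake_fed = awm_logistic(L = 25 + 0.6 * j, k = 0.13 + 0.01 * j,
                              x0 = 12 + 0.3 * j, lag = lags[i]),
      urban = awm_linear(m = 0.75 + 0.05 * j, b = 3.5 + 0.3 * j,
                         lag = lags[i]))
    northern <- i %in% c(5, 10, 15, 20)  # a minority of cooler sites
    scens[[i]] <- site_scenario(
      site_id = sprintf("site%02d", i), regime = reg,
      air_params = list(mean = if (northern) 3 else 7 + 0.15 * j,
                        seasonal_amp = if (northern) 15 else 14,
                        diel_amp = 3.5 + 0.4 * j, ar1 = 0.9835,
                        noise_sd = 0.63),
      transfer_truth = transfer,
      stream_noise_sd = 0.15, stream_ar1 = 0.8)
  }
  names(scens) <- vapply(scens, `[[`, character(1), "site_id")
  scens
}

#' Default per-site acclimation means
#'
#' Twenty 30-day acclimation means spread evenly over 9.09--18.63 degC, the
#' observed span of site 30-day mean stream temperatures in the motivating
#' field study. Used when fish are simulated without simulating temperatures.
#'
#' @param n_sites number of sites.
#' @return Named numeric vector (degC).
#' @export
default_site_acc_means <- function(n_sites = 20) {
  stats::setNames(seq(9.09, 18.63, length.out = n_sites),
                  sprintf("site%02d", seq_len(n_sites)))
}

#' Default trial times
#'
#' One trial per site, staggered every 6 days from mid-June, starting at
#' 12:00 local time (field trials began late morning to early afternoon).
#'
#' @param n_sites number of sites.
#' @param tz timezone.
#' @return Named POSIXct vector.
#' @export
default_trial_times <- function(n_sites = 20, tz = "UTC") {
  t0 <- as.POSIXct("2021-06-15 12:00:00", tz = tz)
  stats::setNames(t0 + (seq_len(n_sites) - 1) * 6 * 86400,
                  sprintf("site%02d", seq_len(n_sites)))
}

#' Simulate a complete study
#'
#' Runs the full generator for a roster of scenarios: air and stream series
#' per site over the season (with a pre-season spin-up long enough to cover
#' the longest acclimation window), per-site acclimation means at the trial
#' time, and fish records.
#'
#' @param scenarios list of [site_scenario] (default [default_scenarios()]).
#' @param truth a [population_truth].
#' @param season POSIXct length-2: the analysis window (default
#'   1 May--31 Oct 2021, the seasonal window of the motivating study).
#' @param trial_times named POSIXct vector per site.
#' @param n_per_site fish per site.
#' @param acc_window_days window (days) whose mean drives the true
#'   acclimation effect (default 30).
#' @param seed integer seed.
#' @param p_unrecovered probability a fish fails to recover.
#' @return A list of class `ctmax_study`: `air`, `stream` (named lists of
#'   [temp_series]), `fish` (a `fish_records` frame), `acc_means`,
#'   `trial_times`, `scenarios`, `truth`, `season`.
#' @export
simulate_study <- function(scenarios = default_scenarios(),
                           truth = population_truth(),
                           season = default_season(),
                           trial_times = default_trial_times(length(scenarios)),
                           n_per_site = 19,
                           acc_window_days = 30,
                           seed = 1,
                           p_unrecovered = 0.025) {
  spinup_h <- 45 * 24  # covers the 40-day window plus the longest lag
  air <- list(); stream <- list()
  names(trial_times) <- names(scenarios)[seq_along(trial_times)]
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    a <- simulate_air(sc, season[1] - spinup_h * 3600, season[2],
                      seed = seed * 1000L + i)
    s <- simulate_stream(a, sc, seed = seed * 1000L + 500L + i)
    air[[sc$site_id]] <- a
    stream[[sc$site_id]] <- s
  }
  acc <- vapply(names(stream), function(sid) {
    window_mean(stream[[sid]], trial_times[[sid]], acc_window_days)$mean
  }, numeric(1))
  fish <- simulate_fish(truth, acc, n_per_site = n_per_site,
                        seed = seed * 1000L + 999L,
                        trial_times = trial_times,
                        p_unrecovered = p_unrecovered)
  structure(list(air = air, stream = stream, fish = fish, acc_means = acc,
                 trial_times = trial_times, scenarios = scenarios,
                 truth = truth, season = season),
            class = "ctmax_study")
}

#' Default analysis season (1 May to 31 October 2021, inclusive)
#' @param tz timezone.
#' @return POSIXct length-2 vector; the window is used half-open, so the end
#'   bound is 1 November 00:00.
#' @export
default_season <- function(tz = "UTC") {
  c(as.POSIXct("2021-05-01 00:00:00", tz = tz),
    as.POSIXct("2021-11-01 00:00:00", tz = tz))
}
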