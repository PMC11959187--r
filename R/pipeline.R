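#' Study configuration
#'
#' The pipeline is driven by one YAML config listing the per-site input
#' files and the analysis constants: the seasonal window, lag grid,
#' candidate acclimation windows, sublethal thresholds, ramp QA band,
#' coverage floors and the seed. All paths are resolved relative to the
#' config file's directory and must exist at load time.
#'
#' @param path path to a YAML config file.
#' @return A list of class `study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  tz <- cfg$timezone %||% "UTC"
  defaults <- list(windows = c(1, 4, 8, 14, 30, 40),
                   thresholds = c(20, 22.5),
                   ramp_band = c(3.89, 4.09),
                   coverage_floor = 0.8, min_overlap = 72,
                   lag_grid = list(min = 0, max = 72), seed = 1)
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  stopifnot(all(unlist(cfg$windows) > 0),
            all(unlist(cfg$windows) == round(unlist(cfg$windows))))
  cfg$season <- c(as.POSIXct(cfg$season$start, tz = tz),
                  as.POSIXct(cfg$season$end, tz = tz))
  cfg$fish_csv <- file.path(base, cfg$fish_csv)
  for (i in seq_along(cfg$sites)) {
    cfg$sites[[i]]$air_csv <- file.path(base, cfg$sites[[i]]$air_csv)
    cfg$sites[[i]]$stream_csv <- file.path(base, cfg$sites[[i]]$stream_csv)
    cfg$sites[[i]]$trial_time <- as.POSIXct(cfg$sites[[i]]$trial_time,
                                            tz = tz)
  }
  paths <- c(cfg$fish_csv,
             vapply(cfg$sites, `[[`, character(1), "air_csv"),
             vapply(cfg$sites, `[[`, character(1), "stream_csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("config references missing file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cfg$timezone <- tz
  class(cfg) <- "study_config"
  cfg
}

read_fish_csv <- function(path, tz = "UTC") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "site_id", "fork_length_mm", "mass_g", "ctmax",
            "recovered")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("fish CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$recovered <- as.logical(df$recovered)
  if ("trial_time" %in% names(df)) {
    df$trial_time <- as.POSIXct(df$trial_time, tz = tz)
  }
  class(df) <- c("fish_records", "data.frame")
  df
}

#' Validate study inputs
#'
#' Checks file schemas and timestamps, duplicate fish ids, unrecovered-fish
#' exclusions and per-site in-season logger coverage, distinguishing errors
#' (must fix) from warnings (noted).
#'
#' @param config a `study_config` from [read_study_config()].
#' @return A list of class `validation_report`: `errors`, `warnings`,
#'   `exclusions` (unrecovered fish ids), `n_fish`, `n_sites`.
#' @export
validate_inputs <- function(config) {
  errors <- character(); warnings_ <- character()
  fish <- tryCatch(read_fish_csv(config$fish_csv, config$timezone),
                   error = function(e) {errors <<- c(errors,
                     conditionMessage(e)); NULL})
  excl <- character()
  if (!is.null(fish)) {
    dup <- fish$fish_id[duplicated(fish$fish_id)]
    if (length(dup)) {
      errors <- c(errors, paste("duplicated fish id(s):",
                                paste(unique(dup), collapse = ", ")))
    }
    excl <- fish$fish_id[!fish$recovered]
    if (length(excl)) {
      warnings_ <- c(warnings_, sprintf(
        "%d fish did not recover and are excluded from all fits",
        length(excl)))
    }
    cfg_sites <- vapply(config$sites, `[[`, character(1), "site_id")
    orphan <- setdiff(unique(fish$site_id), cfg_sites)
    if (length(orphan)) {
      errors <- c(errors, paste("fish at unconfigured site(s):",
                                paste(orphan, collapse = ", ")))
    }
  }
  for (s in config$sites) {
    stream <- tryCatch(
      read_series(s$stream_csv, timezone = config$timezone,
                  site_id = s$site_id),
      error = function(e) {errors <<- c(errors, conditionMessage(e)); NULL})
    if (is.null(stream)) next
    w <- restrict_window(resample_hourly(stream), config$season[1],
                         config$season[2])
    expected <- as.numeric(difftime(config$season[2], config$season[1],
                                    units = "hours"))
    cov <- nrow(w) / expected
    if (cov < 0.25) {
      warnings_ <- c(warnings_, sprintf(
        "site %s: only %.0f%% of season hours recorded; imputation will dominate",
        s$site_id, 100 * cov))
    }
  }
  structure(list(errors = errors, warnings = warnings_, exclusions = excl,
                 n_fish = if (is.null(fish)) NA_integer_ else nrow(fish),
                 n_sites = length(config$sites)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s sites, %s fish; %d error(s), %d warning(s)\n",
              x$n_sites, x$n_fish, length(x$errors), length(x$warnings)))
  if (length(x$errors)) cat(paste0("  ERROR: ", x$errors, "\n"), sep = "")
  if (length(x$warnings)) cat(paste0("  warn:  ", x$warnings, "\n"), sep = "")
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Executes impute, metrics, model and TSM stages for a configured study
#' and writes all stage outputs under `out_dir`: completed per-site series
#' (`completed/<site>.csv`), a transfer-model report
#' (`impute_report.json`), the acclimation table and thermal-regime
#' summaries (CSV), the window-selection ranking (CSV), and a combined
#' `summary.json` (best window, slope with SE, marginal/conditional
#' R-squared, per-site TSMs, ARR). Deterministic: the same config produces
#' byte-identical summary output.
#'
#' @param config a `study_config` or path to one.
#' @param out_dir output directory (created if needed).
#' @return The result bundle, invisibly: list with `models`, `completed`,
#'   `acclimation`, `regime`, `ranking`, `additive`, `tsm`, `arr`,
#'   `summary`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_study_config(config)
  dir.create(file.path(out_dir, "completed"), recursive = TRUE,
             showWarnings = FALSE)
  season <- config$season
  lag_grid <- seq(config$lag_grid$min, config$lag_grid$max)
  fish <- read_fish_csv(config$fish_csv, config$timezone)
  trial_times <- stats::setNames(
    as.POSIXct(vapply(config$sites, function(s)
      as.character(s$trial_time), character(1)), tz = config$timezone),
    vapply(config$sites, `[[`, character(1), "site_id"))

  # --- impute stage -------------------------------------------------------
  completed <- list(); model_report <- list()
  for (s in config$sites) {
    air <- resample_hourly(read_series(s$air_csv, timezone = config$timezone,
                                       site_id = paste0(s$site_id, "_air")))
    stream <- resample_hourly(read_series(s$stream_csv,
                                          timezone = config$timezone,
                                          site_id = s$site_id))
    model <- tryCatch(
      fit_transfer(air, stream, candidate_lags = lag_grid,
                   min_overlap = config$min_overlap, window = season),
      error = function(e) stop("impute stage, site ", s$site_id, ": ",
                               conditionMessage(e), call. = FALSE))
    pred <- predict_stream(model, air)
    filled_start <- min(season[1], trial_times[[s$site_id]] -
                          max(unlist(config$windows)) * 86400)
    comp <- suppressWarnings(
      fill_gaps(stream, pred, filled_start, season[2]))
    completed[[s$site_id]] <- comp
    write_series(comp, file.path(out_dir, "completed",
                                 paste0(s$site_id, ".csv")))
    model_report[[s$site_id]] <- list(
      kind = model$kind, lag = model$lag, r2 = model$fit_r2,
      n = model$n_obs,
      params = if (model$kind == "linear") list(m = model$m, b = model$b)
               else list(L = model$L, k = model$k, x0 = model$x0),
      fraction_recorded = attr(comp, "fraction_recorded"))
    message(sprintf("[impute] %s: %s model, lag %d h, R2 %.3f",
                    s$site_id, model$kind, model$lag, model$fit_r2))
  }
  jsonlite::write_json(model_report,
                       file.path(out_dir, "impute_report.json"),
                       auto_unbox = TRUE, digits = 10)

  # --- metrics stage ------------------------------------------------------
  acc <- acclimation_table(completed, trial_times,
                           windows = unlist(config$windows),
                           coverage_floor = config$coverage_floor)
  utils::write.csv(acc, file.path(out_dir, "acclimation_table.csv"),
                   row.names = FALSE)
  regime <- do.call(rbind, lapply(completed, thermal_regime_summary,
                                  season = season,
                                  thresholds = unlist(config$thresholds)))
  utils::write.csv(regime, file.path(out_dir, "thermal_regime.csv"),
                   row.names = FALSE)

  # --- model stage --------------------------------------------------------
  ranking <- select_window(fish, acc, windows = unlist(config$windows))
  utils::write.csv(as.data.frame(ranking),
                   file.path(out_dir, "window_selection.csv"),
                   row.names = FALSE)
  best_w <- attr(ranking, "best_window")
  slope_w <- if (is.na(best_w)) {
    ws <- unlist(config$windows)
    if (30 %in% ws) 30 else ws[1]  # null model won: report the 30-day slope
  } else best_w
  best_acc <- acc[acc$window_days == slope_w, ]
  per_fish_acc <- best_acc$mean_temp[match(fish$site_id, best_acc$site_id)]
  best_fit <- attr(ranking, "fits")[[sprintf("%dd", slope_w)]]
  additive <- if (sum(fish$recovered) >= 30) {
    fit_additive(fish, per_fish_acc)
  } else {
    message("[model] fewer than 30 recovered fish; additive model skipped")
    NULL
  }
  sites_sum <- site_effect_summary(best_fit, fish)
  utils::write.csv(sites_sum, file.path(out_dir, "site_effects.csv"),
                   row.names = FALSE)

  # --- tsm stage ----------------------------------------------------------
  tsm_tab <- tsm_table(fish, completed, season,
                       thresholds = unlist(config$thresholds),
                       trial_times = trial_times)
  utils::write.csv(tsm_tab, file.path(out_dir, "tsm.csv"),
                   row.names = FALSE)
  arr_res <- arr(best_fit)

  summary <- list(
    n_fish_included = sum(fish$recovered),
    n_sites = length(completed),
    best_window_days = best_w,
    acclimation_slope = unname(best_fit$beta[2]),
    acclimation_slope_se = unname(best_fit$beta_se[2]),
    r2_marginal = best_fit$r2_marginal,
    r2_conditional = best_fit$r2_conditional,
    arr = arr_res$arr,
    body_peak_mm = if (is.null(additive)) NA else additive$body_peak_mm,
    deviance_explained = if (is.null(additive)) NA else
      additive$dev_explained,
    tsm = stats::setNames(as.list(tsm_tab$tsm), tsm_tab$site_id))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(list(models = model_report, completed = completed,
                 acclimation = acc, regime = regime, ranking = ranking,
                 additive = additive, site_effects = sites_sum,
                 tsm = tsm_tab, arr = arr_res, summary = summary))
}

#' Write a complete synthetic fixture study to disk
#'
#' Emits the CSV/YAML bundle the pipeline readers accept: per-site air and
#' stream CSVs (the stream series masked with logger-style gaps so the
#' impute stage has work to do), a fish CSV, and a `config.yml`. A small
#' toy study (default 20 sites) generates in seconds.
#'
#' @param dir output directory.
#' @param seed integer seed for the generator.
#' @param n_sites number of sites.
#' @param n_per_site fish per site.
#' @param gap_fraction random fraction of in-season stream hours to mask.
#' @return The config file path, invisibly.
#' @export
write_fixture_study <- function(dir, seed = 1, n_sites = 20,
                                n_per_site = 19, gap_fraction = 0.15) {
  scen <- default_scenarios(n_sites)
  study <- simulate_study(scen, trial_times = default_trial_times(n_sites),
                          n_per_site = n_per_site, seed = seed)
  dir.create(file.path(dir, "air"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "stream"), recursive = TRUE,
             showWarnings = FALSE)
  sites <- list()
  for (sid in names(study$stream)) {
    write_series(study$air[[sid]], file.path(dir, "air",
                                             paste0(sid, "_air.csv")))
    masked <- mask_gaps(study$stream[[sid]], fraction = gap_fraction,
                        seed = seed + match(sid, names(study$stream)))
    write_series(masked, file.path(dir, "stream",
                                   paste0(sid, "_stream.csv")))
    sites[[length(sites) + 1]] <- list(
      site_id = sid,
      air_csv = file.path("air", paste0(sid, "_air.csv")),
      stream_csv = file.path("stream", paste0(sid, "_stream.csv")),
      trial_time = format(study$trial_times[[sid]], "%Y-%m-%d %H:%M:%S"))
  }
  fish <- as.data.frame(study$fish)
  fish$trial_time <- format(fish$trial_time, "%Y-%m-%d %H:%M:%S")
  utils::write.csv(fish, file.path(dir, "fish.csv"), row.names = FALSE)
  cfg <- list(timezone = "UTC",
              season = list(start = format(study$season[1],
                                           "%Y-%m-%d %H:%M:%S"),
                            end = format(study$season[2],
                                         "%Y-%m-%d %H:%M:%S")),
              fish_csv = "fish.csv",
              seed = seed,
              sites = sites)
  yaml::write_yaml(cfg, file.path(dir, "config.yml"))
  invisible(file.path(dir, "config.yml"))
}
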