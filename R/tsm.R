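#' Thermal safety margin for a site
#'
#' TSM is the site's mean CTmax minus the maximum stream temperature
#' (recorded or imputed) over the season. The report also carries the
#' sublethal variants (threshold minus seasonal maximum), hours above each
#' threshold, and whether the seasonal maximum fell within the 30 days
#' before the trial (if a trial time is supplied).
#'
#' @param site_ctmax numeric vector of CTmax values (degC) for included,
#'   i.e. recovered, fish at the site.
#' @param series the site's completed hourly [temp_series].
#' @param season POSIXct length-2 window (default 1 May--31 Oct).
#' @param thresholds sublethal thresholds (degC), default 20 and 22.5 (the
#'   optimum-range ceiling and the sublethal physiological threshold for
#'   brook trout).
#' @param trial_time optional POSIXct trial start for the 30-day flag.
#' @return A one-row data frame of class `tsm_report`: `site_id`, `n_fish`,
#'   `mean_ctmax`, `season_max`, `season_max_time`, `tsm`, one
#'   `sublethal_tsm_<th>` and `hours_above_<th>` column per threshold, and
#'   `max_in_30day_window`.
#' @export
tsm <- function(site_ctmax, series, season = default_season(),
                thresholds = c(20, 22.5), trial_time = NULL) {
  if (!length(site_ctmax)) stop("need at least one fish", call. = FALSE)
  sm <- seasonal_max(series, season[1], season[2])
  out <- data.frame(site_id = site_id(series),
                    n_fish = length(site_ctmax),
                    mean_ctmax = mean(site_ctmax),
                    season_max = sm$max,
                    season_max_time = sm$datetime,
                    tsm = mean(site_ctmax) - sm$max)
  exc <- exceedance(series, thresholds, season)
  for (th in thresholds) {
    out[[sprintf("sublethal_tsm_%g", th)]] <- sublethal_tsm(series, th, season)
    out[[sprintf("hours_above_%g", th)]] <-
      exc$hours_above[exc$threshold == th]
  }
  out$max_in_30day_window <- if (!is.null(trial_time) && !is.na(trial_time)) {
    sm$datetime >= trial_time - 30 * 86400 & sm$datetime < trial_time
  } else NA
  class(out) <- c("tsm_report", "data.frame")
  out
}

#' Sublethal thermal safety margin
#'
#' Threshold temperature minus the seasonal maximum stream temperature.
#' Negative values are meaningful: the site exceeds the threshold at some
#' point in the season.
#'
#' @param series completed hourly [temp_series].
#' @param threshold sublethal threshold (degC).
#' @param season POSIXct length-2 window.
#' @return Numeric (degC).
#' @export
sublethal_tsm <- function(series, threshold = 22.5,
                          season = default_season()) {
  threshold - seasonal_max(series, season[1], season[2])$max
}

#' Threshold exceedance summary
#'
#' Hours with temperature strictly above each threshold, plus an
#' any-exceedance flag. Counts are taken on the hourly series; sub-hourly
#' spikes are outside the resolution of the analysis.
#'
#' @param series hourly [temp_series].
#' @param thresholds thresholds (degC).
#' @param season POSIXct length-2 window.
#' @return A data frame: `threshold`, `hours_above`, `exceeded`.
#' @export
exceedance <- function(series, thresholds = c(20, 22.5),
                       season = default_season()) {
  w <- restrict_window(series, season[1], season[2])
  data.frame(threshold = thresholds,
             hours_above = vapply(thresholds, function(th)
               sum(w$temp_c > th), numeric(1)),
             exceeded = vapply(thresholds, function(th)
               any(w$temp_c > th), logical(1)))
}

#' Acclimation response ratio
#'
#' The ARR is the change in upper thermal tolerance per unit change in
#' acclimation temperature. The individual-level basis takes the fixed
#' acclimation slope (and its SE) straight from a fitted mixed model; the
#' site-mean basis regresses site mean CTmax on site acclimation mean by
#' OLS. Values below 1 indicate partial plastic compensation.
#'
#' @param fit a `ctmax_lmm` whose covariate is an acclimation mean
#'   (individual-level basis), or `NULL` if `site_means` is given.
#' @param site_means optional data frame with columns `acc` and `ctmax`
#'   (site means) for the site-mean basis.
#' @return A list of class `arr_result`: `arr`, `se`, `basis`.
#' @export
arr <- function(fit = NULL, site_means = NULL) {
  if (!is.null(fit)) {
    if (length(fit$beta) < 2) {
      stop("fit has no acclimation slope (null model?)", call. = FALSE)
    }
    res <- list(arr = unname(fit$beta[2]), se = unname(fit$beta_se[2]),
                basis = "individual-level slope")
  } else if (!is.null(site_means)) {
    if (stats::var(site_means$acc) == 0) {
      stop("degenerate acclimation spread across sites", call. = FALSE)
    }
    ols <- stats::summary.lm(stats::lm(ctmax ~ acc, data = site_means))
    res <- list(arr = unname(ols$coefficients["acc", "Estimate"]),
                se = unname(ols$coefficients["acc", "Std. Error"]),
                basis = "site-mean slope")
  } else stop("supply `fit` or `site_means`", call. = FALSE)
  class(res) <- "arr_result"
  res
}

#' @export
print.arr_result <- function(x, ...) {
  cat(sprintf("<arr_result> ARR = %.3f degC/degC (SE %.3f), basis: %s\n",
              x$arr, x$se, x$basis))
  invisible(x)
}

#' Assemble the per-site TSM table for a study
#'
#' Runs [tsm()] for every site and stacks the one-row reports.
#'
#' @param fish a `fish_records` data frame (unrecovered fish excluded).
#' @param streams named list of completed hourly [temp_series].
#' @param season POSIXct length-2 window.
#' @param thresholds sublethal thresholds (degC).
#' @param trial_times optional named POSIXct vector per site.
#' @return A data frame with one `tsm_report` row per site.
#' @export
tsm_table <- function(fish, streams, season = default_season(),
                      thresholds = c(20, 22.5), trial_times = NULL) {
  keep <- if ("recovered" %in% names(fish)) fish$recovered else TRUE
  fish <- fish[keep, ]
  rows <- lapply(names(streams), function(sid) {
    ct <- fish$ctmax[fish$site_id == sid]
    tt <- if (!is.null(trial_times)) trial_times[[sid]] else NULL
    tsm(ct, streams[[sid]], season, thresholds, tt)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot site thermal metrics and safety margins
#'
#' Two-panel summary in the style of field TSM figures: site mean CTmax,
#' seasonal maximum and mean daytime temperature in the upper panel and TSM
#' in the lower, sites ordered by increasing mean CTmax. Requires ggplot2.
#'
#' @param tsm_tab output of [tsm_table()].
#' @param daytime optional named numeric vector of mean daytime temperature
#'   per site.
#' @return A ggplot object.
#' @export
plot_tsm <- function(tsm_tab, daytime = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_tsm requires ggplot2", call. = FALSE)
  }
  ord <- order(tsm_tab$mean_ctmax)
  tab <- tsm_tab[ord, ]
  tab$site_rank <- factor(seq_len(nrow(tab)), labels = tab$site_id)
  long <- rbind(
    data.frame(site_rank = tab$site_rank, value = tab$mean_ctmax,
               metric = "mean CTmax", panel = "temperature"),
    data.frame(site_rank = tab$site_rank, value = tab$season_max,
               metric = "seasonal max", panel = "temperature"),
    data.frame(site_rank = tab$site_rank, value = tab$tsm,
               metric = "TSM", panel = "safety margin"))
  if (!is.null(daytime)) {
    long <- rbind(long, data.frame(
      site_rank = tab$site_rank, value = daytime[as.character(tab$site_id)],
      metric = "mean daytime", panel = "temperature"))
  }
  ggplot2::ggplot(long, ggplot2::aes(
    x = site_rank, y = value, shape = metric)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::facet_grid(panel ~ ., scales = "free_y") +
    ggplot2::labs(x = "site (by increasing mean CTmax)",
                  y = expression(degree * C)) +
    ggplot2::theme_bw()
}
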