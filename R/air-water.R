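#' Air-to-stream transfer models
#'
#' Stream temperature in small streams tracks air temperature with a time
#' lag, linearly over moderate ranges and sigmoidally once evaporative
#' cooling and snowmelt/groundwater buffering flatten the response at the
#' extremes. Two model families are supported:
#' \describe{
#'   \item{linear}{`T_stream = m * T_air(lagged) + b`}
#'   \item{logistic}{`T_stream = L / (1 + exp(-k * (T_air(lagged) - x0)))`,
#'     with `L` the maximum of the curve, `k` the logistic growth rate and
#'     `x0` the sigmoid inflection point.}
#' }
#' `awm_linear()` and `awm_logistic()` build model objects directly (used as
#' ground truth by the synthetic generator); [fit_linear()] and
#' [fit_logistic()] estimate them from aligned air/stream pairs.
#'
#' @param m,b linear slope (degC per degC) and intercept (degC).
#' @param L,k,x0 logistic maximum (degC), growth rate (per degC) and
#'   inflection point (degC).
#' @param lag non-negative whole number of hours by which stream lags air.
#' @param fit_r2 coefficient of determination of the fit (NA for truth
#'   objects).
#' @param n_obs number of pairs used in fitting.
#' @return An object of class `air_water_model`.
#' @name air_water_model
NULL

#' @rdname air_water_model
#' @export
awm_linear <- function(m, b, lag = 0, fit_r2 = NA_real_, n_obs = NA_integer_) {
  stopifnot(is.finite(m), is.finite(b), lag >= 0)
  structure(list(kind = "linear", m = m, b = b, L = NULL, k = NULL,
                 x0 = NULL, lag = as.integer(lag), fit_r2 = fit_r2,
                 n_obs = n_obs, degenerate = FALSE),
            class = "air_water_model")
}

#' @rdname air_water_model
#' @export
awm_logistic <- function(L, k, x0, lag = 0, fit_r2 = NA_real_,
                         n_obs = NA_integer_) {
  stopifnot(L > 0, is.finite(k), is.finite(x0), lag >= 0)
  structure(list(kind = "logistic", m = NULL, b = NULL, L = L, k = k,
                 x0 = x0, lag = as.integer(lag), fit_r2 = fit_r2,
                 n_obs = n_obs, degenerate = FALSE),
            class = "air_water_model")
}

#' @export
print.air_water_model <- function(x, ...) {
  if (x$kind == "linear") {
    cat(sprintf("<air_water_model> linear: T_stream = %.4f * T_air + %.4f\n",
                x$m, x$b))
  } else {
    cat(sprintf(
      "<air_water_model> logistic: L = %.4f, k = %.4f, x0 = %.4f\n",
      x$L, x$k, x$x0))
  }
  cat(sprintf("  lag = %d h, R2 = %s, n = %s%s\n", x$lag,
              format(x$fit_r2, digits = 4), format(x$n_obs),
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

# Evaluate a transfer model on raw air temperatures (no lag handling).
transfer_eval <- function(model, air_c) {
  switch(model$kind,
         linear = model$m * air_c + model$b,
         logistic = model$L / (1 + exp(-model$k * (air_c - model$x0))),
         stop("unknown model kind: ", model$kind))
}

#' Pair stream observations with lagged air observations
#'
#' Builds the regression sample `(T_air(t - lag), T_stream(t))` over all
#' timestamps where both series have a point. Both series must be hourly.
#'
#' @param air,stream hourly [temp_series] objects.
#' @param lag non-negative whole number of hours.
#' @param min_overlap minimum number of pairs required (default 72, i.e.
#'   three days of hourly data, a floor for a 3-parameter curve under
#'   autocorrelated noise).
#' @return A data frame with columns `datetime` (stream time), `air`,
#'   `stream`.
#' @export
align_lagged <- function(air, stream, lag, min_overlap = 72) {
  if (lag < 0 || lag != round(lag)) {
    stop("`lag` must be a non-negative whole number of hours", call. = FALSE)
  }
  idx <- match(as.numeric(stream$datetime) - lag * 3600,
               as.numeric(air$datetime))
  keep <- !is.na(idx)
  pairs <- data.frame(datetime = stream$datetime[keep],
                      air = air$temp_c[idx[keep]],
                      stream = stream$temp_c[keep])
  if (nrow(pairs) < min_overlap) {
    stop(sprintf(
      "insufficient overlap: %d pairs at lag %d h (need >= %d)",
      nrow(pairs), as.integer(lag), as.integer(min_overlap)), call. = FALSE)
  }
  pairs
}

#' Choose the air-to-stream lag by linear-model fit
#'
#' Scans a candidate grid of lags and returns the one whose ordinary linear
#' regression of stream on lagged air has the highest R-squared; ties are
#' broken toward the smallest lag.
#'
#' @inheritParams align_lagged
#' @param candidate_lags integer vector of candidate lags in hours
#'   (default 0 to 72).
#' @return The selected lag (integer hours), with the per-lag R-squared grid
#'   in attribute `r2_by_lag`.
#' @export
best_lag <- function(air, stream, candidate_lags = 0:72, min_overlap = 72) {
  if (!length(candidate_lags)) stop("empty candidate lag set", call. = FALSE)
  if (stats::var(stream$temp_c) == 0) {
    stop("stream series is constant; lag R-squared undefined", call. = FALSE)
  }
  candidate_lags <- sort(unique(as.integer(candidate_lags)))
  r2 <- rep(NA_real_, length(candidate_lags))
  last_err <- NULL
  for (i in seq_along(candidate_lags)) {
    pairs <- tryCatch(
      align_lagged(air, stream, candidate_lags[i], min_overlap),
      error = function(e) {last_err <<- e; NULL})
    if (is.null(pairs)) next
    if (stats::var(pairs$air) == 0 || stats::var(pairs$stream) == 0) next
    r2[i] <- stats::cor(pairs$air, pairs$stream)^2
  }
  if (all(is.na(r2))) {
    stop("no feasible lag in candidate set: ",
         conditionMessage(last_err %||% simpleError("degenerate pairs")),
         call. = FALSE)
  }
  best <- candidate_lags[which.max(r2)]  # which.max takes the first maximum
  structure(best, r2_by_lag = stats::setNames(r2, candidate_lags))
}

#' Fit the linear transfer model
#'
#' Ordinary least squares of stream temperature on lagged air temperature.
#'
#' @param pairs data frame from [align_lagged()].
#' @param lag lag (hours) recorded in the returned model.
#' @return An `air_water_model` of kind `"linear"` with `fit_r2` computed on
#'   the fitting pairs.
#' @export
fit_linear <- function(pairs, lag = 0) {
  if (nrow(pairs) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(pairs$air) == 0) {
    stop("zero variance in air temperature; slope unidentifiable",
         call. = FALSE)
  }
  fit <- stats::lm(stream ~ air, data = pairs)
  r2 <- r_squared(pairs$stream, stats::fitted(fit))
  awm_linear(m = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]),
             lag = lag, fit_r2 = r2, n_obs = nrow(pairs))
}

r_squared <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(NA_real_)
  max(0, min(1, 1 - sum((obs - pred)^2) / sst))
}

#' Fit the logistic transfer model
#'
#' Nonlinear least squares via the Levenberg--Marquardt algorithm
#' (`minpack.lm::nlsLM`). The starting values exploit the identity that the
#' logistic derivative at `x0` is `k * L / 4`: `L` starts at 1.05 times the
#' maximum observed stream temperature, `x0` at the median air temperature,
#' and `k` at four times the OLS slope over `L`. Up to `restarts` jittered
#' restarts are attempted on failure. A fitted `L` above `max_L` is flagged
#' degenerate (the sigmoid has collapsed to a near-line and the asymptote is
#' not identified).
#'
#' @param pairs data frame from [align_lagged()].
#' @param init optional named list/vector with starting `L`, `k`, `x0`.
#' @param lag lag (hours) recorded in the returned model.
#' @param max_L plausibility bound for the fitted maximum (default 60 degC).
#' @param restarts maximum number of jittered restarts (default 5).
#' @return An `air_water_model` of kind `"logistic"`; attribute `convergence`
#'   holds iterations and success flag.
#' @export
fit_logistic <- function(pairs, init = NULL, lag = 0, max_L = 60,
                         restarts = 5) {
  if (nrow(pairs) < 10) stop("need at least 10 pairs", call. = FALSE)
  if (stats::var(pairs$air) == 0) {
    stop("zero spread in air temperature", call. = FALSE)
  }
  if (is.null(init)) {
    ols <- stats::coef(stats::lm(stream ~ air, data = pairs))
    L0 <- 1.05 * max(pairs$stream)
    if (L0 <= 0) L0 <- 1
    init <- list(L = L0, x0 = stats::median(pairs$air),
                 k = max(4 * ols[[2]] / L0, 1e-3))
  }
  start <- list(L = init$L, k = init$k, x0 = init$x0)
  attempt <- 0L
  fit <- NULL
  best_so_far <- start
  repeat {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        stream ~ L / (1 + exp(-k * (air - x0))),
        data = pairs, start = start,
        lower = c(L = 1e-3, k = 1e-6, x0 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (!inherits(fit, "error")) break
    attempt <- attempt + 1L
    if (attempt > restarts) {
      stop(sprintf(
        "logistic fit failed to converge after %d restarts (%s); best-so-far: L=%.3g k=%.3g x0=%.3g",
        restarts, conditionMessage(fit), best_so_far$L, best_so_far$k,
        best_so_far$x0), call. = FALSE)
    }
    # deterministic jitter so refits of the same data are reproducible
    jit <- with_seed(1000L + attempt, stats::runif(3, 0.6, 1.4))
    start <- list(L = init$L * jit[1], k = init$k * jit[2],
                  x0 = init$x0 + (jit[3] - 1) * 10)
    best_so_far <- start
  }
  est <- stats::coef(fit)
  r2 <- r_squared(pairs$stream, stats::fitted(fit))
  model <- awm_logistic(L = est[["L"]], k = est[["k"]], x0 = est[["x0"]],
                        lag = lag, fit_r2 = r2, n_obs = nrow(pairs))
  model$degenerate <- est[["L"]] > max_L
  attr(model, "convergence") <- list(
    iterations = fit$convInfo$finIter %||% NA_integer_,
    success = isTRUE(fit$convInfo$isConv), restarts_used = attempt)
  model
}

#' Select the better transfer model by observed-vs-predicted R-squared
#'
#' For each candidate, regresses observed stream temperatures on the model's
#' predictions and compares the resulting R-squared values; the higher wins.
#' An exact tie goes to the linear model (parsimony), and a model with
#' degenerate (zero-variance or flagged-degenerate) predictions loses
#' automatically.
#'
#' @param linear,logistic fitted `air_water_model` objects on the same pairs.
#' @param pairs the fitting pairs.
#' @return The winning model, with both R-squared values in attribute
#'   `selection_r2`.
#' @export
select_model <- function(linear, logistic, pairs) {
  obs_pred_r2 <- function(model) {
    if (isTRUE(model$degenerate)) return(NA_real_)
    pred <- transfer_eval(model, pairs$air)
    if (stats::var(pred) == 0) return(NA_real_)
    stats::cor(pairs$stream, pred)^2
  }
  r2_lin <- obs_pred_r2(linear)
  r2_log <- obs_pred_r2(logistic)
  if (is.na(r2_lin) && is.na(r2_log)) {
    stop("both models produce degenerate predictions", call. = FALSE)
  }
  chosen <- if (is.na(r2_log)) linear
    else if (is.na(r2_lin)) logistic
    else if (r2_log > r2_lin) logistic else linear
  attr(chosen, "selection_r2") <- c(linear = r2_lin, logistic = r2_log)
  chosen
}

#' Predict stream temperature from air temperature
#'
#' Evaluates the transfer model on every air observation and stamps the
#' prediction at the air timestamp shifted forward by the model's lag. All
#' predictions are flagged `imputed`.
#'
#' @param model a fitted or true `air_water_model`.
#' @param air an hourly [temp_series] of air temperature.
#' @return A [temp_series] of predicted stream temperatures.
#' @export
predict_stream <- function(model, air) {
  pred <- transfer_eval(model, air$temp_c)
  temp_series(air$datetime + model$lag * 3600, pred, "imputed",
              site_id = site_id(air))
}

#' Complete a recorded series with model predictions
#'
#' Within the window, hours present in the recorded series keep their
#' recorded values untouched; hours absent from it take the predicted value,
#' flagged `imputed`. Recorded data are never overwritten. Hours missing from
#' both series are left absent, with a warning listing how many.
#'
#' @param recorded hourly [temp_series] of logger data.
#' @param predicted hourly [temp_series] from [predict_stream()].
#' @param start,end POSIXct bounds of the half-open completion window.
#' @return A [temp_series] with attribute `fraction_recorded`.
#' @export
fill_gaps <- function(recorded, predicted, start, end) {
  rec <- restrict_window(recorded, start, end)
  prd <- restrict_window(predicted, start, end)
  extra <- !(as.numeric(prd$datetime) %in% as.numeric(rec$datetime))
  out <- rbind(as.data.frame(rec),
               data.frame(datetime = prd$datetime[extra],
                          temp_c = prd$temp_c[extra],
                          source = rep("imputed", sum(extra))))
  out <- out[order(out$datetime), , drop = FALSE]
  expected <- seq(from = ceil_hour(start), to = end - 1, by = 3600)
  n_absent <- sum(!(as.numeric(expected) %in% as.numeric(out$datetime)))
  if (n_absent > 0) {
    warning(sprintf("%d hour(s) in window missing from both series",
                    n_absent), call. = FALSE)
  }
  res <- ts_rebuild(out, site_id(recorded))
  attr(res, "fraction_recorded") <-
    if (nrow(res)) mean(res$source == "recorded") else NA_real_
  res
}

ceil_hour <- function(t) {
  tz <- attr(t, "tzone") %||% "UTC"
  as.POSIXct(ceiling(as.numeric(t) / 3600) * 3600, tz = tz,
             origin = "1970-01-01")
}

#' Fit, select and lag-search in one call
#'
#' Convenience wrapper running [best_lag()], [fit_linear()],
#' [fit_logistic()] and [select_model()] on a pair of hourly series,
#' restricted to a fitting window if given.
#'
#' @inheritParams best_lag
#' @param window optional POSIXct length-2 vector restricting the fitting
#'   data (the seasonal window over which the air-water relation is
#'   approximately monotone).
#' @return The selected `air_water_model` (the rejected model is attached as
#'   attribute `rejected`).
#' @export
fit_transfer <- function(air, stream, candidate_lags = 0:72,
                         min_overlap = 72, window = NULL) {
  if (!is.null(window)) {
    air <- restrict_window(air, window[1], window[2])
    stream <- restrict_window(stream, window[1], window[2])
  }
  lag <- best_lag(air, stream, candidate_lags, min_overlap)
  pairs <- align_lagged(air, stream, as.integer(lag), min_overlap)
  lin <- fit_linear(pairs, lag = as.integer(lag))
  log_ <- tryCatch(fit_logistic(pairs, lag = as.integer(lag)),
                   error = function(e) NULL)
  if (is.null(log_)) {
    attr(lin, "rejected") <- NULL
    return(lin)
  }
  chosen <- select_model(lin, log_, pairs)
  attr(chosen, "rejected") <- if (chosen$kind == "linear") log_ else lin
  chosen
}
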