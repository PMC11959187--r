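#' Random-intercept linear mixed model for CTmax
#'
#' Fits `y = X beta + u_site + e`, `u_site ~ N(0, sigma_u^2)`,
#' `e ~ N(0, sigma_e^2)`, by maximum (or restricted maximum) likelihood.
#' The fit profiles `beta` and `sigma_e^2` out of the Gaussian likelihood
#' and optimises the single remaining parameter, the variance ratio
#' `lambda = sigma_u^2 / sigma_e^2`, in one dimension; for a grouped
#' random intercept all the required inverses have closed forms
#' (`(I + lambda*J)^{-1} = I - lambda/(1 + lambda*n_i) * J` per site), so
#' each likelihood evaluation is linear in the number of records. The
#' boundary `sigma_u^2 = 0` is always evaluated and may be returned.
#'
#' `AIC = -2 logLik + 2 n_params` with `n_params` = fixed coefficients + 2
#' variance components; AIC values are comparable across fixed-effect
#' structures only for ML fits, which is why model selection in
#' [select_window()] uses ML.
#'
#' @param records a `fish_records` data frame (or any data frame with
#'   `site_id`, `ctmax` and logical `recovered`); fish with
#'   `recovered = FALSE` are excluded before fitting.
#' @param covariate per-fish numeric fixed-effect covariate (e.g. the
#'   acclimation-window mean at the fish's site, or fork length), aligned
#'   with `records` rows; `NULL` fits the intercept-only (null) model.
#' @param method `"ML"` (default) or `"REML"`.
#' @param covariate_name label for the covariate column in output.
#' @return An object of class `ctmax_lmm`: list with `beta`, `beta_se`,
#'   `sigma_u2`, `sigma_e2`, `loglik`, `n_params`, `aic`, `r2_marginal`,
#'   `r2_conditional`, `site_effects` (shrunken intercept predictions),
#'   `method`, `n`, `n_sites`, `fitted_fixed`.
#' @seealso [r2_nakagawa()], [select_window()]
#' @export
fit_lmm <- function(records, covariate = NULL, method = c("ML", "REML"),
                    covariate_name = "covariate") {
  method <- match.arg(method)
  if (!is.null(covariate) && length(covariate) != nrow(records)) {
    stop("`covariate` must align with `records` rows", call. = FALSE)
  }
  keep <- if ("recovered" %in% names(records)) records$recovered else
    rep(TRUE, nrow(records))
  y <- records$ctmax[keep]
  g <- factor(records$site_id[keep])
  X <- if (is.null(covariate)) {
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    matrix(c(rep(1, length(y)), as.numeric(covariate[keep])), ncol = 2,
           dimnames = list(NULL, c("(Intercept)", covariate_name)))
  }
  if (length(y) < 3) stop("need at least 3 records", call. = FALSE)
  if (qr(X)$rank < ncol(X)) {
    stop("singular fixed-effect design (constant covariate?)", call. = FALSE)
  }
  fit <- lmm_profile_fit(y, X, g, method)
  out <- structure(c(fit, list(method = method, n = length(y),
                               n_sites = nlevels(g))),
                   class = "ctmax_lmm")
  r2 <- r2_nakagawa(out)
  out$r2_marginal <- r2$r2_marginal
  out$r2_conditional <- r2$r2_conditional
  out
}

# Profiled log-likelihood machinery. For fixed lambda = sigma_u2/sigma_e2,
# with per-site closed-form inverse of (I + lambda J):
#   A' V^-1 B = sum_i [A_i'B_i - lambda/(1+lambda n_i) (sum A_i)'(sum B_i)]
#   log|V|    = sum_i log(1 + lambda n_i)
lmm_lambda_eval <- function(lambda, y, X, g, method) {
  n <- length(y); p <- ncol(X)
  idx <- split(seq_len(n), g)
  ni <- lengths(idx)
  XtVX <- matrix(0, p, p); XtVy <- numeric(p)
  yty <- 0
  for (j in seq_along(idx)) {
    ii <- idx[[j]]
    Xi <- X[ii, , drop = FALSE]; yi <- y[ii]
    w <- lambda / (1 + lambda * ni[j])
    sx <- colSums(Xi); sy <- sum(yi)
    XtVX <- XtVX + crossprod(Xi) - w * tcrossprod(sx)
    XtVy <- XtVy + crossprod(Xi, yi) - w * sx * sy
    yty <- yty + sum(yi^2) - w * sy^2
  }
  beta <- solve(XtVX, XtVy)
  q <- as.numeric(yty - 2 * sum(beta * XtVy) +
                    as.numeric(crossprod(beta, XtVX %*% beta)))
  q <- max(q, 1e-12)
  logdetV <- sum(log1p(lambda * ni))
  if (method == "ML") {
    sigma_e2 <- q / n
    ll <- -0.5 * (n * log(2 * pi * sigma_e2) + logdetV + n)
  } else {
    sigma_e2 <- q / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * sigma_e2) + logdetV +
                    determinant(XtVX, logarithm = TRUE)$modulus + (n - p))
  }
  list(loglik = as.numeric(ll), beta = as.numeric(beta),
       sigma_e2 = sigma_e2, XtVX = XtVX, lambda = lambda)
}

lmm_profile_fit <- function(y, X, g, method) {
  n <- length(y); p <- ncol(X)
  obj <- function(t) lmm_lambda_eval(exp(t), y, X, g, method)$loglik
  # coarse scan then local refinement; boundary lambda = 0 checked explicitly
  tgrid <- seq(-14, 12, length.out = 53)
  llg <- vapply(tgrid, obj, numeric(1))
  i <- which.max(llg)
  lo <- tgrid[max(1, i - 1)]; hi <- tgrid[min(length(tgrid), i + 1)]
  opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.4)
  best0 <- lmm_lambda_eval(0, y, X, g, method)
  best <- lmm_lambda_eval(exp(opt$maximum), y, X, g, method)
  if (best0$loglik >= best$loglik) best <- best0
  if (!is.finite(best$loglik)) {
    stop("mixed-model likelihood did not converge; trace: ",
         paste(sprintf("%.2f", range(llg, finite = TRUE)), collapse = " .. "),
         call. = FALSE)
  }
  lambda <- best$lambda
  sigma_e2 <- best$sigma_e2
  sigma_u2 <- lambda * sigma_e2
  beta <- best$beta
  names(beta) <- colnames(X)
  vcov_beta <- sigma_e2 * solve(best$XtVX)
  fitted_fixed <- as.numeric(X %*% beta)
  r <- y - fitted_fixed
  rs <- tapply(r, g, sum)
  ni <- tapply(rep(1, length(y)), g, sum)
  u <- lambda * rs / (1 + lambda * ni)   # BLUP shrinkage toward 0
  n_params <- p + 2
  list(beta = beta, beta_se = sqrt(diag(vcov_beta)), vcov_beta = vcov_beta,
       sigma_u2 = sigma_u2, sigma_e2 = sigma_e2, lambda = lambda,
       loglik = best$loglik, n_params = n_params,
       aic = -2 * best$loglik + 2 * n_params,
       site_effects = stats::setNames(as.numeric(u), names(rs)),
       fitted_fixed = fitted_fixed)
}

#' @export
print.ctmax_lmm <- function(x, ...) {
  cat(sprintf("<ctmax_lmm> %s fit: %d fish, %d sites\n", x$method, x$n,
              x$n_sites))
  co <- cbind(Estimate = x$beta, `Std.Error` = x$beta_se)
  print(round(co, 4))
  cat(sprintf("  sigma_u^2 = %.4f, sigma_e^2 = %.4f\n", x$sigma_u2,
              x$sigma_e2))
  cat(sprintf("  logLik = %.3f, AIC = %.2f, R2m = %.3f, R2c = %.3f\n",
              x$loglik, x$aic, x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' Marginal and conditional R-squared for a mixed model
#'
#' Variance-partition R-squared for Gaussian random-intercept models:
#' the marginal value is the share of total variance (fixed + site + residual)
#' attributable to the fixed-effect linear predictor, and the conditional
#' value adds the site-intercept variance to the numerator.
#'
#' @param fit a `ctmax_lmm` from [fit_lmm()].
#' @param fixed_var optional override for the fixed-effect predictor
#'   variance (degC^2); by default the sample variance of the fitted fixed
#'   linear predictor.
#' @return A list: `r2_marginal`, `r2_conditional`.
#' @export
r2_nakagawa <- function(fit, fixed_var = NULL) {
  var_f <- if (is.null(fixed_var)) stats::var(fit$fitted_fixed) else fixed_var
  if (length(fit$fitted_fixed) < 2) var_f <- 0
  total <- var_f + fit$sigma_u2 + fit$sigma_e2
  if (total <= 0) stop("zero total variance", call. = FALSE)
  list(r2_marginal = var_f / total,
       r2_conditional = (var_f + fit$sigma_u2) / total)
}

#' Rank acclimation windows by AIC
#'
#' Fits one ML mixed model per candidate acclimation window (CTmax on the
#' window-mean temperature with a site random intercept) plus the null
#' (intercept + site) model, and ranks them by AIC. Ties in AIC are broken
#' toward the shorter window. Akaike weights are computed over the whole
#' candidate set and accumulated in rank order.
#'
#' @param records a `fish_records` data frame.
#' @param acclimation an acclimation table from [acclimation_table()]
#'   (columns `site_id`, `window_days`, `mean_temp`).
#' @param windows candidate windows in days.
#' @return A data frame of class `window_ranking` with one row per model
#'   (`window_days` is NA for the null model), columns `model`, `K`, `AIC`,
#'   `dAIC`, `weight`, `cum_weight`, `r2_conditional`, `r2_marginal`,
#'   `slope`, `slope_se`; the best window (days) is in attribute
#'   `best_window` and the fitted models in attribute `fits`.
#' @export
select_window <- function(records, acclimation,
                          windows = c(1, 4, 8, 14, 30, 40)) {
  miss <- setdiff(unique(records$site_id), unique(acclimation$site_id))
  if (length(miss)) {
    stop("no window means for site(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  fits <- list()
  rows <- list()
  for (w in windows) {
    sub <- acclimation[acclimation$window_days == w, ]
    miss_w <- setdiff(unique(records$site_id), sub$site_id)
    if (length(miss_w)) {
      stop(sprintf("missing %d-day means for site(s): %s", w,
                   paste(miss_w, collapse = ", ")), call. = FALSE)
    }
    cov <- sub$mean_temp[match(records$site_id, sub$site_id)]
    f <- fit_lmm(records, cov, method = "ML",
                 covariate_name = sprintf("acc_%dd", w))
    fits[[sprintf("%dd", w)]] <- f
    rows[[length(rows) + 1]] <- data.frame(
      model = sprintf("%d-day + (Site)", w), window_days = w, K = f$n_params,
      AIC = f$aic, r2_conditional = f$r2_conditional,
      r2_marginal = f$r2_marginal, slope = unname(f$beta[2]),
      slope_se = unname(f$beta_se[2]))
  }
  fnull <- fit_lmm(records, NULL, method = "ML")
  fits[["null"]] <- fnull
  rows[[length(rows) + 1]] <- data.frame(
    model = "Null", window_days = NA_integer_, K = fnull$n_params,
    AIC = fnull$aic, r2_conditional = fnull$r2_conditional,
    r2_marginal = fnull$r2_marginal, slope = NA_real_, slope_se = NA_real_)
  tab <- do.call(rbind, rows)
  ord <- order(tab$AIC, tab$window_days)  # AIC ties -> shorter window first
  tab <- tab[ord, ]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  w_raw <- exp(-0.5 * tab$dAIC)
  tab$weight <- w_raw / sum(w_raw)
  tab$cum_weight <- cumsum(tab$weight)
  tab <- tab[, c("model", "window_days", "K", "AIC", "dAIC", "weight",
                 "cum_weight", "r2_conditional", "r2_marginal", "slope",
                 "slope_se")]
  rownames(tab) <- NULL
  attr(tab, "best_window") <- tab$window_days[1]
  attr(tab, "fits") <- fits
  class(tab) <- c("window_ranking", "data.frame")
  tab
}

#' @export
print.window_ranking <- function(x, ...) {
  cat("<window_ranking> acclimation-window model selection (ML)\n")
  df <- as.data.frame(x)
  df[, sapply(df, is.numeric)] <- round(df[, sapply(df, is.numeric)], 3)
  print(df)
  bw <- attr(x, "best_window")
  cat("best window:", if (is.na(bw)) "null model" else paste0(bw, " days"),
      "\n")
  invisible(x)
}

#' Per-site CTmax summary and shrinkage intercepts
#'
#' Raw per-site mean and range of CTmax alongside the model's shrunken
#' site-intercept predictions, plus the Pearson correlation between site
#' mean and site range (sites with one fish have no range and are excluded
#' from the correlation with a warning).
#'
#' @param fit a `ctmax_lmm`.
#' @param records the `fish_records` the model was fitted to.
#' @return A data frame (site, n, mean_ctmax, range_ctmax,
#'   shrunken_intercept) with the mean-range correlation in attribute
#'   `cor_mean_range`.
#' @export
site_effect_summary <- function(fit, records) {
  rec <- records[if ("recovered" %in% names(records)) records$recovered
                 else TRUE, ]
  spl <- split(rec$ctmax, rec$site_id)
  out <- data.frame(
    site_id = names(spl),
    n = lengths(spl),
    mean_ctmax = vapply(spl, mean, numeric(1)),
    range_ctmax = vapply(spl, function(v)
      if (length(v) > 1) diff(range(v)) else NA_real_, numeric(1)))
  out$shrunken_intercept <- fit$site_effects[out$site_id]
  usable <- !is.na(out$range_ctmax)
  if (any(!usable)) {
    warning(sum(!usable), " site(s) with n = 1 excluded from the mean-range",
            " correlation", call. = FALSE)
  }
  attr(out, "cor_mean_range") <- if (sum(usable) >= 3) {
    stats::cor(out$mean_ctmax[usable], out$range_ctmax[usable])
  } else NA_real_
  rownames(out) <- NULL
  out
}
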