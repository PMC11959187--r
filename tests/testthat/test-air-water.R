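test_that("align_lagged pairs stream with lag-shifted air and counts overlap", {
  air <- make_hourly(1:200, site = "a")
  stream <- make_hourly(1:200, site = "s")
  p0 <- align_lagged(air, stream, 0)
  expect_equal(p0$air, p0$stream)
  # stream shifted 6 h relative to air pairs perfectly at lag 6
  stream6 <- temp_series(air$datetime + 6 * 3600, air$temp_c, site_id = "s")
  p6 <- align_lagged(air, stream6, 6)
  expect_equal(p6$air, p6$stream)
  expect_equal(nrow(p6), 200)
  expect_error(align_lagged(air, stream, 2.5), "whole number")
  expect_error(align_lagged(air, make_hourly(1:10), 0), "insufficient overlap")
})

test_that("align_lagged pair count equals a brute-force intersection on gappy series", {
  set.seed(11)
  air <- make_hourly(runif(400, 0, 20), site = "a")
  stream <- make_hourly(runif(400, 5, 15), site = "s")
  airg <- mask_gaps(air, fraction = 0.3, seed = 1)
  streamg <- mask_gaps(stream, fraction = 0.3, seed = 2)
  lag <- 5
  pairs <- align_lagged(airg, streamg, lag)
  oracle_n <- sum((as.numeric(streamg$datetime) - lag * 3600) %in%
                    as.numeric(airg$datetime))
  expect_equal(nrow(pairs), oracle_n)
})

test_that("best_lag recovers a noiseless shifted-linear lag exactly", {
  sc <- site_scenario("bl", transfer_truth = awm_linear(0.8, 3, lag = 6),
                      stream_noise_sd = 0)
  air <- simulate_air(sc, utc("2021-05-01"), utc("2021-06-15"), seed = 21)
  st <- simulate_stream(air, sc, seed = 1)
  expect_equal(as.integer(best_lag(air, st, 0:24)), 6L)
})

test_that("best_lag agrees with an exhaustive R-squared grid on unrelated series", {
  set.seed(13)
  air <- make_hourly(runif(300, -5, 25), site = "a")
  stream <- make_hourly(runif(300, 5, 15), site = "s")
  lag <- best_lag(air, stream, 0:12, min_overlap = 48)
  grid <- vapply(0:12, function(l) {
    p <- align_lagged(air, stream, l, min_overlap = 48)
    cor(p$air, p$stream)^2
  }, numeric(1))
  expect_equal(as.integer(lag), (0:12)[which.max(grid)])
  expect_equal(unname(attr(lag, "r2_by_lag")), grid, tolerance = 1e-12)
})

test_that("best_lag rejects a constant stream", {
  air <- make_hourly(runif(100, 0, 20), site = "a")
  flat <- make_hourly(rep(7, 100), site = "s")
  expect_error(best_lag(air, flat, 0:5, min_overlap = 24), "constant")
})

test_that("fit_linear recovers exact coefficients and matches normal equations", {
  x <- seq(-5, 25, length.out = 50)
  exact <- data.frame(air = x, stream = 0.5 * x + 2)
  m <- fit_linear(exact)
  expect_equal(m$m, 0.5, tolerance = 1e-12)
  expect_equal(m$b, 2, tolerance = 1e-12)
  expect_equal(m$fit_r2, 1, tolerance = 1e-12)

  flat <- data.frame(air = x, stream = rep(7, 50))
  mf <- fit_linear(flat)
  expect_equal(mf$m, 0, tolerance = 1e-12)
  expect_equal(mf$b, 7, tolerance = 1e-12)

  set.seed(3)
  noisy <- data.frame(air = runif(10, 0, 20))
  noisy$stream <- 0.7 * noisy$air + 1 + rnorm(10, 0, 0.5)
  mn <- fit_linear(noisy)
  # closed-form normal-equations oracle
  sxx <- sum((noisy$air - mean(noisy$air))^2)
  sxy <- sum((noisy$air - mean(noisy$air)) * (noisy$stream - mean(noisy$stream)))
  expect_equal(mn$m, sxy / sxx, tolerance = 1e-10)
  expect_equal(mn$b, mean(noisy$stream) - sxy / sxx * mean(noisy$air),
               tolerance = 1e-10)
  expect_error(fit_linear(data.frame(air = rep(1, 5), stream = 1:5)),
               "variance")
})

test_that("fit_logistic recovers exact parameters from clean sigmoid data", {
  x <- seq(-10, 30, length.out = 300)
  pairs <- data.frame(air = x, stream = 20 / (1 + exp(-0.2 * (x - 10))))
  m <- fit_logistic(pairs)
  expect_equal(m$L, 20, tolerance = 1e-6)
  expect_equal(m$k, 0.2, tolerance = 1e-6)
  expect_equal(m$x0, 10, tolerance = 1e-6)
  expect_equal(m$fit_r2, 1, tolerance = 1e-9)
  expect_false(m$degenerate)
  # midpoint identity holds for the fitted model
  expect_equal(transfer_eval(m, m$x0), m$L / 2, tolerance = 1e-9)
})

test_that("fit_logistic SSR matches a coarse-grid plus local-polish oracle on noisy data", {
  set.seed(17)
  x <- runif(2000, -10, 30)
  y <- 20 / (1 + exp(-0.2 * (x - 10))) + rnorm(2000, 0, 0.5)
  pairs <- data.frame(air = x, stream = y)
  m <- fit_logistic(pairs)
  ssr_fit <- sum((y - transfer_eval(m, x))^2)
  # oracle: coarse grid then optim() polish, entirely separate code path
  ssr_of <- function(p) sum((y - p[1] / (1 + exp(-p[2] * (x - p[3]))))^2)
  grid <- expand.grid(L = seq(5, 40, by = 2.5),
                      k = exp(seq(log(0.01), log(1), length.out = 12)),
                      x0 = seq(-5, 25, by = 2.5))
  ssr_grid <- apply(grid, 1, ssr_of)
  start <- as.numeric(grid[which.min(ssr_grid), ])
  pol <- stats::optim(start, ssr_of, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  expect_lt(abs(ssr_fit - pol$value) / pol$value, 1e-6)
})

test_that("select_model prefers the family that predicts better, linear on ties", {
  x <- seq(-10, 30, length.out = 400)
  # strongly curved truth -> logistic wins
  curved <- data.frame(air = x,
                       stream = 18 / (1 + exp(-0.35 * (x - 12))))
  lin <- fit_linear(curved)
  log_ <- fit_logistic(curved)
  sel <- select_model(lin, log_, curved)
  expect_equal(sel$kind, "logistic")
  r2s <- attr(sel, "selection_r2")
  expect_gte(r2s["logistic"], r2s["linear"])

  # exactly linear truth -> linear returned by the tie/parsimony rule
  straight <- data.frame(air = x, stream = 0.6 * x + 4)
  lin2 <- fit_linear(straight)
  log2 <- fit_logistic(straight)
  sel2 <- select_model(lin2, log2, straight)
  expect_equal(sel2$kind, "linear")

  # degenerate logistic loses automatically
  log_bad <- log2
  log_bad$degenerate <- TRUE
  expect_equal(select_model(lin2, log_bad, straight)$kind, "linear")
})

test_that("predict_stream evaluates the formula at lag-shifted stamps, flagged imputed", {
  air <- make_hourly(runif(100, -5, 25), site = "a")
  ident <- awm_linear(1, 0, lag = 0)
  p <- predict_stream(ident, air)
  expect_equal(p$temp_c, air$temp_c)
  expect_true(all(p$source == "imputed"))

  m <- awm_logistic(20, 0.2, 10, lag = 6)
  p2 <- predict_stream(m, air)
  expect_equal(p2$datetime, air$datetime + 6 * 3600)
  idx <- sample(100, 50)
  expect_equal(p2$temp_c[idx],
               20 / (1 + exp(-0.2 * (air$temp_c[idx] - 10))),
               tolerance = 1e-12)
  # asymptote: very cold air maps just above zero, below any recorded minimum
  cold <- make_hourly(rep(-40, 24), site = "c")
  expect_true(all(predict_stream(m, cold)$temp_c > 0))
  expect_true(all(predict_stream(m, cold)$temp_c < 1e-2))
})

test_that("fill_gaps keeps every recorded value and fills only the holes", {
  full <- make_hourly(seq(10, by = 0.05, length.out = 120), site = "s")
  start <- full$datetime[1]; end <- full$datetime[120] + 3600
  pred <- temp_series(full$datetime, full$temp_c + 5, "imputed",
                      site_id = "s")
  # complete recorded input: output identical, fraction 1
  out <- fill_gaps(full, pred, start, end)
  expect_equal(out$temp_c, full$temp_c)
  expect_equal(attr(out, "fraction_recorded"), 1)
  # empty recorded input: output equals predictions, fraction 0
  empty <- restrict_window(full, start - 86400, start)
  out0 <- fill_gaps(empty, pred, start, end)
  expect_equal(out0$temp_c, pred$temp_c)
  expect_equal(attr(out0, "fraction_recorded"), 0)
  # alternating gaps: per-hour source flags match the hand-built oracle
  gappy <- ts_subset <- as.data.frame(full)[seq(1, 120, by = 2), ]
  gappy <- temp_series(gappy$datetime, gappy$temp_c, gappy$source, "s")
  out_alt <- fill_gaps(gappy, pred, start, end)
  expect_equal(nrow(out_alt), 120)
  expect_equal(out_alt$source,
               rep(c("recorded", "imputed"), 60))
  expect_equal(out_alt$temp_c[seq(1, 120, by = 2)], gappy$temp_c)
  expect_equal(out_alt$temp_c[seq(2, 120, by = 2)],
               pred$temp_c[seq(2, 120, by = 2)])
  # hours missing from both produce a warning
  short_pred <- restrict_window(pred, start, full$datetime[60])
  expect_warning(fill_gaps(gappy, short_pred, start, end), "missing")
})

test_that("fit_transfer recovers kind, lag and parameters on clean synthetic data", {
  sc <- site_scenario("pipe", transfer_truth = awm_logistic(16, 0.22, 11,
                                                            lag = 9),
                      stream_noise_sd = 0)
  air <- simulate_air(sc, utc("2021-04-15"), utc("2021-08-01"), seed = 41)
  st <- simulate_stream(air, sc, seed = 1)
  m <- fit_transfer(air, st, candidate_lags = 0:24)
  expect_equal(m$kind, "logistic")
  expect_equal(m$lag, 9L)
  expect_equal(m$L, 16, tolerance = 1e-6)
  expect_equal(m$k, 0.22, tolerance = 1e-6)
  expect_equal(m$x0, 11, tolerance = 1e-6)
})
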