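test_that("window_mean averages the half-open pre-trial window with coverage", {
  ts <- make_hourly(rep(12, 72), start = "2021-06-01 00:00:00")
  trial <- utc("2021-06-03 00:00:00")
  wm <- window_mean(ts, trial, 2)
  expect_equal(wm$mean, 12)
  expect_equal(wm$coverage, 1)
  # hand-computable fixture: mean of the 48 hours before the trial
  vals <- seq(5, by = 0.25, length.out = 72)
  ts2 <- make_hourly(vals, start = "2021-06-01 00:00:00")
  wm2 <- window_mean(ts2, trial, 2)
  # half-open at the trial: the hour starting at the trial time is excluded
  expect_equal(wm2$mean, mean(vals[1:48]))
  expect_error(window_mean(ts, utc("2021-09-01 00:00:00"), 1), "coverage")
})

test_that("window_mean enforces the coverage floor and reports recorded fraction", {
  ts <- make_hourly(rep(10, 48), start = "2021-06-01 00:00:00")
  gappy <- mask_gaps(ts, fraction = 0.5, seed = 2)
  expect_error(window_mean(gappy, utc("2021-06-03 00:00:00"), 2), "coverage")
  wm <- window_mean(gappy, utc("2021-06-03 00:00:00"), 2,
                    coverage_floor = 0.3)
  expect_equal(wm$coverage, 0.5)
})

test_that("diel_stats applies the 18-hour rule and matches a day-by-day oracle", {
  # constant series: zero fluctuation
  ts <- make_hourly(rep(9, 96), start = "2021-06-01 00:00:00")
  ds <- diel_stats(ts, ts$datetime[1], ts$datetime[96] + 3600)
  expect_equal(ds$mean_diel, 0)
  expect_equal(ds$max_diel, 0)

  # pure diel sinusoid of amplitude A: fluctuation ~ 2A up to discretization
  hod <- rep(0:23, 4)
  sine <- make_hourly(15 + 3 * sin(2 * pi * hod / 24),
                      start = "2021-06-01 00:00:00")
  ds2 <- diel_stats(sine, sine$datetime[1], sine$datetime[96] + 3600)
  expect_equal(ds2$mean_diel, 6, tolerance = 0.05)
  expect_equal(ds2$max_diel, 6, tolerance = 0.05)

  # gappy fixture: drop day 2 to 12 h; oracle respects the 18-hour rule
  set.seed(5)
  vals <- runif(96, 8, 20)
  full <- make_hourly(vals, start = "2021-06-01 00:00:00")
  drop_idx <- 25:36  # 12 hours of day 2 remain -> day 2 disqualified
  gappy <- temp_series(full$datetime[-drop_idx], vals[-drop_idx],
                       site_id = "g")
  ds3 <- diel_stats(gappy, full$datetime[1], full$datetime[96] + 3600)
  per_day <- vapply(c(1, 3, 4), function(d) {
    v <- vals[(24 * (d - 1) + 1):(24 * d)]
    max(v) - min(v)
  }, numeric(1))
  expect_equal(ds3$n_days, 3)
  expect_equal(ds3$mean_diel, mean(per_day))
  expect_equal(ds3$max_diel, max(per_day))
  expect_error(diel_stats(gappy, full$datetime[25], full$datetime[49]),
               "18 hours|no day")
})

test_that("seasonal_max returns the earliest maximum and matches a linear scan", {
  rising <- make_hourly(1:50)
  sm <- seasonal_max(rising, rising$datetime[1], rising$datetime[50] + 3600)
  expect_equal(sm$max, 50)
  expect_equal(sm$datetime, rising$datetime[50])
  # tie -> earliest
  vals <- c(1, 9, 3, 9, 2)
  tied <- make_hourly(vals)
  sm2 <- seasonal_max(tied, tied$datetime[1], tied$datetime[5] + 3600)
  expect_equal(sm2$datetime, tied$datetime[2])
  # random fixture equals linear-scan oracle
  set.seed(23)
  v <- runif(500, 0, 25)
  rnd <- make_hourly(v)
  sm3 <- seasonal_max(rnd, rnd$datetime[1], rnd$datetime[500] + 3600)
  expect_equal(sm3$max, max(v))
  expect_equal(sm3$datetime, rnd$datetime[which.max(v)])
  expect_error(seasonal_max(rnd, rnd$datetime[1] - 7200, rnd$datetime[1]),
               "empty")
})

test_that("daytime_mean filters on local clock time", {
  # series that is 10 at night and 20 during 09:00-19:00
  hod <- as.integer(format(make_hourly(rep(0, 72))$datetime, "%H"))
  vals <- ifelse(hod >= 9 & hod < 19, 20, 10)
  ts <- make_hourly(vals)
  expect_equal(daytime_mean(ts, ts$datetime[1], ts$datetime[72] + 3600), 20)
  # constant series gives the constant
  cst <- make_hourly(rep(13.5, 48))
  expect_equal(daytime_mean(cst, cst$datetime[1], cst$datetime[48] + 3600),
               13.5)
  # mixed fixture equals filter-then-mean oracle
  set.seed(9)
  v <- runif(72, 5, 25)
  mx <- make_hourly(v)
  expect_equal(daytime_mean(mx, mx$datetime[1], mx$datetime[72] + 3600),
               mean(v[hod >= 9 & hod < 19]))
})

test_that("ramp_rate recovers the OLS slope and applies the QA band", {
  t0 <- utc("2021-07-01 12:00:00")
  tsec <- seq(0, 3600 * 2, by = 15)
  exact <- temp_series(t0 + tsec, 15 + 4 * tsec / 3600, site_id = "r")
  rr <- ramp_rate(exact)
  expect_equal(rr$rate, 4, tolerance = 1e-10)
  expect_true(rr$qa_pass)
  slow <- temp_series(t0 + tsec, 15 + 3.5 * tsec / 3600, site_id = "r")
  expect_false(ramp_rate(slow)$qa_pass)
  # jittered ramp equals the closed-form OLS oracle
  set.seed(12)
  y <- 15 + 4 * tsec / 3600 + rnorm(length(tsec), 0, 0.05)
  jit <- temp_series(t0 + tsec, y, site_id = "r")
  h <- tsec / 3600
  slope_oracle <- sum((h - mean(h)) * (y - mean(y))) / sum((h - mean(h))^2)
  expect_equal(ramp_rate(jit)$rate, slope_oracle, tolerance = 1e-10)
  expect_error(ramp_rate(temp_series(t0 + 0:5, 1:6, site_id = "r")),
               ">= 10")
})

test_that("acclimation_table produces one row per site and window", {
  streams <- list(
    s1 = make_hourly(rep(10, 45 * 24), start = "2021-05-01 00:00:00",
                     site = "s1"),
    s2 = make_hourly(rep(15, 45 * 24), start = "2021-05-01 00:00:00",
                     site = "s2"))
  tt <- c(s1 = utc("2021-06-14 12:00:00"), s2 = utc("2021-06-14 12:00:00"))
  tab <- acclimation_table(streams, tt, windows = c(1, 4, 8, 14, 30, 40))
  expect_equal(nrow(tab), 12)
  expect_equal(unique(tab$mean_temp[tab$site_id == "s1"]), 10)
  expect_equal(unique(tab$mean_temp[tab$site_id == "s2"]), 15)
  expect_true(all(tab$coverage <= 1))
  expect_error(acclimation_table(streams, c(s1 = utc("2021-06-14"))),
               "no trial time")
})

test_that("metrics are unchanged by imputed points outside the window", {
  ts <- make_hourly(runif(48, 10, 14), start = "2021-06-01 00:00:00")
  trial <- utc("2021-06-03 00:00:00")
  before <- window_mean(ts, trial, 2)
  extended <- temp_series(c(ts$datetime, trial + 3600 * (1:24)),
                          c(ts$temp_c, rep(99, 24)),
                          c(ts$source, rep("imputed", 24)), site_id(ts))
  after <- window_mean(extended, trial, 2)
  expect_equal(after$mean, before$mean)
})
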