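test_that("simulate_air reduces to the exact annual sinusoid in the deterministic limit", {
  sc <- site_scenario("det", air_params = list(mean = 7, seasonal_amp = 14,
                                               diel_amp = 0, ar1 = 0.9,
                                               noise_sd = 0))
  air <- simulate_air(sc, utc("2021-05-01"), utc("2021-05-03"), seed = 1)
  lt <- as.POSIXlt(air$datetime)
  doy <- lt$yday + lt$hour / 24
  expect_equal(air$temp_c, 7 + 14 * cos(2 * pi * (doy - 200) / 365.25),
               tolerance = 1e-12)
})

test_that("simulate_air is reproducible and rejects bad steps", {
  sc <- site_scenario("rep")
  a <- simulate_air(sc, utc("2021-05-01"), utc("2021-05-05"), seed = 99)
  b <- simulate_air(sc, utc("2021-05-01"), utc("2021-05-05"), seed = 99)
  expect_identical(a$temp_c, b$temp_c)
  c_ <- simulate_air(sc, utc("2021-05-01"), utc("2021-05-05"), seed = 100)
  expect_false(identical(a$temp_c, c_$temp_c))
  expect_error(simulate_air(sc, utc("2021-05-01"), utc("2021-05-05"),
                            step_hours = -1), "positive")
  expect_error(simulate_air(sc, utc("2021-05-01"), utc("2021-05-05"),
                            step_hours = 7), "divide")
  expect_error(simulate_air(sc, utc("2021-05-05"), utc("2021-05-01")),
               "precede")
})

test_that("air noise component is mean-zero across replicates", {
  sc <- site_scenario("nz", air_params = list(mean = 0, seasonal_amp = 0,
                                              diel_amp = 0, ar1 = 0.7,
                                              noise_sd = 0.5))
  # one long draw: AR(1) stationary mean 0; SE accounts for autocorrelation
  air <- simulate_air(sc, utc("2021-01-01"), utc("2022-05-01"), seed = 5)
  n <- nrow(air)
  phi <- 0.7
  se <- 0.5 / sqrt(1 - phi^2) * sqrt((1 + phi) / (1 - phi) / n)
  expect_lt(abs(mean(air$temp_c)), 3 * se)
})

test_that("simulate_stream applies the lagged transfer exactly at zero noise", {
  # logistic midpoint identity: air held at x0 maps to L/2
  sc <- site_scenario("mid", transfer_truth = awm_logistic(20, 0.2, 10,
                                                           lag = 0),
                      stream_noise_sd = 0,
                      air_params = list(mean = 10, seasonal_amp = 0,
                                        diel_amp = 0, ar1 = 0, noise_sd = 0))
  air <- simulate_air(sc, utc("2021-06-01"), utc("2021-06-05"), seed = 1)
  st <- simulate_stream(air, sc, seed = 1)
  expect_equal(st$temp_c, rep(10, nrow(st)), tolerance = 1e-12)

  # identity transfer: linear m = 1, b = 0, lag 0 reproduces air exactly
  sc2 <- site_scenario("ident", transfer_truth = awm_linear(1, 0, lag = 0),
                       stream_noise_sd = 0)
  air2 <- simulate_air(sc2, utc("2021-06-01"), utc("2021-06-05"), seed = 3)
  st2 <- simulate_stream(air2, sc2, seed = 1)
  expect_equal(st2$temp_c, air2$temp_c)
  expect_true(all(st2$source == "recorded"))
})

test_that("stream output is time-shifted by the true lag and bounded by L plus noise", {
  sc <- site_scenario("lagged", transfer_truth = awm_logistic(18, 0.15, 9,
                                                              lag = 7),
                      stream_noise_sd = 0.2)
  air <- simulate_air(sc, utc("2021-05-01"), utc("2021-06-01"), seed = 2)
  st <- simulate_stream(air, sc, seed = 4)
  expect_equal(st$datetime, air$datetime + 7 * 3600)
  expect_true(all(st$temp_c < 18 + 6 * 0.2 / sqrt(1 - 0.8^2)))
  expect_error(simulate_stream(restrict_window(air, air$datetime[1],
                                               air$datetime[5]), sc),
               "shorter")
})

test_that("groundwater-damped transfer yields a smaller seasonal range than surface", {
  mk <- function(transfer) {
    sc <- site_scenario("x", transfer_truth = transfer, stream_noise_sd = 0)
    air <- simulate_air(sc, utc("2021-05-01"), utc("2021-11-01"), seed = 8)
    st <- simulate_stream(air, sc, seed = 1)
    diff(range(st$temp_c))
  }
  gw <- mk(awm_logistic(13, 0.10, 9, lag = 6))    # small k*L product
  sf <- mk(awm_logistic(22, 0.18, 10, lag = 6))
  expect_lt(gw, sf)
})

test_that("simulate_fish reproduces the linear acclimation structure in the noise-free limit", {
  flat <- population_truth(beta0 = 26, beta_acc = 0.23,
                           body_curve = function(fl) 0 * fl,
                           sigma_site = 0, sigma_resid = 1e-12)
  acc <- c(a = 10, b = 11)
  fish <- simulate_fish(flat, acc, n_per_site = 5, seed = 2)
  expect_equal(fish$ctmax[fish$site_id == "a"], rep(26 + 2.3, 5),
               tolerance = 1e-9)
  # two sites 1 degC apart differ by exactly beta_acc
  expect_equal(mean(fish$ctmax[fish$site_id == "b"]) -
                 mean(fish$ctmax[fish$site_id == "a"]), 0.23,
               tolerance = 1e-9)
  expect_error(simulate_fish(flat, numeric(0)), "empty")
})

test_that("fish records carry plausible covariates and reproducible draws", {
  fish <- simulate_fish(population_truth(), default_site_acc_means(20),
                        n_per_site = 19, seed = 31)
  expect_equal(nrow(fish), 380)
  expect_true(all(fish$fork_length_mm >= 74 & fish$fork_length_mm <= 289))
  expect_gt(cor(fish$fork_length_mm, fish$mass_g), 0.9)
  fish2 <- simulate_fish(population_truth(), default_site_acc_means(20),
                         n_per_site = 19, seed = 31)
  expect_identical(fish$ctmax, fish2$ctmax)
})

test_that("simulate_ramp assigns LOE times on the ramp and flags immediate LOE", {
  fish <- data.frame(fish_id = c("f1", "f2"), ctmax = c(29, 14),
                     site_id = "s")
  tr <- simulate_ramp(15, 4, fish, seed = 1, rate_jitter_sd = 0,
                      temp_jitter_sd = 0)
  # (29 - 15) / 4 = 3.5 h to LOE on an exact ramp
  expect_equal(as.numeric(difftime(tr$loe$loe_time[1], tr$ramp$datetime[1],
                                   units = "hours")), 3.5, tolerance = 1e-6)
  expect_true(tr$loe$immediate_loe[2])
  expect_false(tr$loe$immediate_loe[1])
  expect_error(simulate_ramp(15, -4, fish), "positive")
  # zero jitter -> fitted slope is exactly nominal
  rr <- ramp_rate(tr)
  expect_equal(rr$rate, 4, tolerance = 1e-9)
  expect_equal(rr$resid_sd, 0, tolerance = 1e-9)
  expect_true(rr$qa_pass)
})

test_that("mask_gaps removes exactly what the pattern says and nothing else", {
  ts <- make_hourly(seq(10, by = 0.1, length.out = 240))
  expect_equal(mask_gaps(ts, fraction = 0, seed = 1)$temp_c, ts$temp_c)
  iv <- data.frame(start = ts$datetime[49], end = ts$datetime[72] + 3600)
  masked <- mask_gaps(ts, intervals = iv, seed = 1)
  expect_equal(nrow(masked), 240 - 24)
  expect_false(any(masked$datetime >= iv$start & masked$datetime < iv$end))
  # surviving values unchanged (conservation)
  expect_equal(masked$temp_c,
               ts$temp_c[!(ts$datetime >= iv$start & ts$datetime < iv$end)])
  # random masking is reproducible
  m1 <- mask_gaps(ts, fraction = 0.25, seed = 9)
  m2 <- mask_gaps(ts, fraction = 0.25, seed = 9)
  expect_identical(m1$datetime, m2$datetime)
  expect_equal(nrow(m1), 240 - 60)
  expect_error(mask_gaps(ts, fraction = 1, seed = 1), "all points")
  # gap inventory accounts for every removed point
  expect_equal(sum(attr(masked, "gap_inventory")$n_points), 24)
})

test_that("seeded calls leave the caller RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_fish(population_truth(), c(a = 10), 3, seed = 77))
  expect_identical(.Random.seed, before)
})
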