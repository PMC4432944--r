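test_that("degenerate noise settings produce a constant temperature field", {
  cfg <- synthetic_config(n_years = 1, n_stations = 3,
                          climate_mean_annual = 20,
                          climate_seasonal_amplitude = 0,
                          climate_daily_noise_sd = 0, station_offset_sd = 0,
                          seed = 42)
  st <- simulate_station_temperatures(cfg)
  expect_true(all(st$t_mean == 20))
  expect_true(all(st$t_min <= st$t_mean & st$t_mean <= st$t_max))
})

test_that("the generator is bit-identical under a fixed seed", {
  cfg <- synthetic_config(n_years = 1, n_stations = 2, seed = 42)
  expect_identical(simulate_station_temperatures(cfg),
                   simulate_station_temperatures(cfg))
  expo <- toy_exposure(400)
  s1 <- simulate_mortality(expo, cfg)
  s2 <- simulate_mortality(expo, cfg)
  expect_identical(s1$mortality, s2$mortality)
  # and a different seed changes the draws
  cfg2 <- synthetic_config(n_years = 1, n_stations = 2, seed = 43)
  expect_false(identical(simulate_station_temperatures(cfg2),
                         simulate_station_temperatures(cfg)))
})

test_that("summer mean temperature falls in the subtropical 22-29 degC band", {
  cfg <- synthetic_config(n_years = 10, n_stations = 1,
                          climate_mean_annual = 25.5,
                          climate_seasonal_amplitude = 3.5,
                          climate_daily_noise_sd = 1, station_offset_sd = 0,
                          seed = 7)
  st <- simulate_station_temperatures(cfg)
  mo <- as.integer(format(st$date, "%m"))
  summer <- st$t_mean[mo %in% 6:8]
  expect_gt(mean(summer), 22)
  expect_lt(mean(summer), 29)
  # defaults too: population-average summer climate stays subtropical
  st2 <- simulate_station_temperatures(synthetic_config(n_years = 10, seed = 8))
  summer2 <- st2$t_mean[as.integer(format(st2$date, "%m")) %in% 6:8]
  expect_gt(mean(summer2), 22)
  expect_lt(mean(summer2), 29)
})

test_that("with no structure the daily counts average the baseline rate", {
  cfg <- synthetic_config(n_years = 7, baseline_daily_deaths = 5.4,
                          dow_log_effects = rep(0, 7),
                          seasonal_log_amplitude = 0,
                          true_surface = null_surface(),
                          overdispersion = 1, seed = 3)
  expo <- toy_exposure(7 * 365)
  sim <- simulate_mortality(expo, cfg)
  y <- sim$truth$counts
  se <- sqrt(5.4 / length(y))
  expect_lt(abs(mean(y) - 5.4), 3 * se)
})

test_that("equi-dispersed draws have Pearson dispersion near 1 against the true model", {
  cfg <- synthetic_config(n_years = 7, overdispersion = 1, seed = 9)
  expo <- toy_exposure(7 * 365)
  sim <- simulate_mortality(expo, cfg)
  disp <- mean((sim$truth$counts - sim$truth$mu)^2 / sim$truth$mu)
  expect_lt(abs(disp - 1), 0.1)
  # overdispersed draws inflate the same statistic to about phi
  cfg2 <- synthetic_config(n_years = 7, overdispersion = 1.5, seed = 9)
  sim2 <- simulate_mortality(expo, cfg2)
  disp2 <- mean((sim2$truth$counts - sim2$truth$mu)^2 / sim2$truth$mu)
  expect_lt(abs(disp2 - 1.5), 0.25)
})

test_that("default settings reproduce registry-scale totals over 7 years", {
  st <- small_study(n_years = 7, seed = 21)
  total <- sum(st$agg$count)
  expect_lt(abs(total - 13889), 3 * sqrt(13889))
  # count conservation against the realized expectations
  expect_lt(abs(total - sum(st$truth$mu)), 4 * sqrt(sum(st$truth$mu)))
  # aggregate equals the category sum by construction
  expect_identical(st$agg$count,
                   aggregate_mortality(st$mortality,
                                       heatlag:::icd10_categories)$count)
})

test_that("a null surface leaves counts uncorrelated with same-day temperature", {
  st <- small_study(n_years = 7, seed = 13)
  # season drives both; partial out the seasonal cycle before correlating
  doy <- as.integer(format(st$agg$date, "%j"))
  y_res <- resid(lm(st$agg$count ~ sin(2 * pi * doy / 365) + cos(2 * pi * doy / 365)))
  x_res <- resid(lm(st$exposure$temp ~ sin(2 * pi * doy / 365) + cos(2 * pi * doy / 365)))
  r <- cor(y_res, x_res)
  expect_lt(abs(r), 3 / sqrt(length(y_res)))
})

test_that("invalid generator settings are rejected", {
  expect_error(synthetic_config(climate_daily_noise_sd = -1), "non-negative")
  expect_error(synthetic_config(climate_seasonal_amplitude = -2), "non-negative")
  expect_error(synthetic_config(overdispersion = 0.5), ">= 1")
  expect_error(synthetic_config(n_stations = 2, station_weights = c(1, 2, 3)),
               "length")
  expect_error(synthetic_config(station_weights = rep(0, 5)), "positive")
  cfg <- synthetic_config(seed = 1)
  expect_error(simulate_mortality(toy_exposure(5), cfg), "at least")
})

test_that("the injected surface is zero at its reference for every lag", {
  s <- rr_surface_spec("threshold_linear", 20, c(0.03, 0.01, rep(0, 9)))
  expect_identical(s$eval(20, 0:10), rep(0, 11))
  expect_identical(s$eval(15, 0:10), rep(0, 11))   # no cold effect
  expect_equal(s$eval(25, 0), 0.15)
  q <- rr_surface_spec("quadratic_above_reference", 20, c(0.01, rep(0, 10)))
  expect_equal(q$eval(23, 0), 0.09)
  expect_identical(q$eval(20, 0:10), rep(0, 11))
})

test_that("warm-up days are flagged and carry truncated history", {
  surface <- rr_surface_spec("threshold_linear", 18, rep(0.02, 11))
  cfg <- synthetic_config(n_years = 1, true_surface = surface, seed = 2,
                          overdispersion = 1)
  x <- rep(25, 365)  # constant hot exposure
  sim <- simulate_mortality(x, cfg)
  expect_identical(which(sim$truth$warmup), 1:10)
  # day 1 sees only lag 0 of the effect; day 11 sees all 11 lags
  expect_lt(sim$truth$mu[1], sim$truth$mu[11])
})
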