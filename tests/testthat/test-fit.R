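test_that("strata assignment follows the calendar and fixed-window schemes", {
  d1 <- seq(as.Date("2004-01-01"), as.Date("2004-01-31"), by = "day")
  expect_equal(nlevels(make_strata(d1)), 1)
  d7 <- seq(as.Date("2004-01-01"), as.Date("2010-12-31"), by = "day")
  expect_equal(nlevels(make_strata(d7)), 84)          # 7 years x 12 months
  s28 <- make_strata(d1[1:31] + 0, "fixed_window", window = 28)
  expect_equal(as.character(s28[28]), "w001")
  expect_equal(as.character(s28[29]), "w002")
  expect_error(make_strata(d1, "fixed_window", window = 6), "degenerate")
  expect_error(make_strata(d1[c(1, 3)]), "contiguous")
})

test_that("an intercept-only fit on constant counts recovers log(c) exactly", {
  d <- as.Date("2004-01-01") + 0:29
  fit <- cc_fit(rep(7L, 30), cb = NULL, dates = d,
                strata = make_strata(d), dow = FALSE)
  expect_equal(unname(coef(fit)[1]), log(7), tolerance = 1e-9)
  expect_equal(fit$k, 1L)
})

test_that("quasi-Poisson coefficients match an independent likelihood maximizer", {
  # 60 days, 2 strata, 4 cross-basis columns
  x <- toy_exposure(60, seed = 41)
  spec <- cb_spec(max_lag = 3, var_df = 2, var_degree = 1, lag_df = 2)
  cb <- crossbasis(x, spec = spec)
  d <- as.Date("2004-01-01") + 0:59
  strata <- make_strata(d)
  set.seed(42)
  y <- rpois(60, exp(1.6 + 0.02 * (x - 20)))
  fit <- cc_fit(y, cb, dates = d, strata = strata)
  des <- build_design(cb, d, strata)
  o <- optim(rep(0, ncol(des$X)), negll_poisson, negll_grad,
             X = des$X, y = y[des$keep], method = "BFGS",
             control = list(maxit = 5000, reltol = 1e-15))
  expect_lt(max(abs(unname(coef(fit)) - o$par)), 1e-6)
  # score equations vanish at the reported optimum
  mu <- exp(drop(des$X %*% unname(coef(fit))))
  expect_lt(max(abs(t(des$X) %*% (y[des$keep] - mu))), 1e-6)
})

test_that("the fit agrees with stats::glm on coefficients and covariance", {
  st <- small_study(n_years = 2, seed = 19)
  cb <- crossbasis(st$exposure, spec = cb_spec())
  fit <- cc_fit(st$agg, cb)
  dat <- data.frame(y = st$agg$count,
                    sf = make_strata(st$exposure$date),
                    dw = heatlag:::dow_factor(st$exposure$date))
  dat$cbm <- unclass(cb)
  ref <- glm(y ~ cbm + sf + dw, quasipoisson(), dat,
             subset = attr(cb, "valid"),
             control = glm.control(epsilon = 1e-10))
  co <- coef(ref)
  names(co) <- sub("^cbm", "", names(co))
  expect_equal(unname(coef(fit)[fit$cb_names]), unname(co[fit$cb_names]),
               tolerance = 1e-6)
  sref <- summary(ref)
  expect_equal(fit$dispersion, sref$dispersion, tolerance = 1e-6)
  vref <- sref$cov.scaled
  rownames(vref) <- colnames(vref) <- names(co)
  expect_equal(fit$vcov[fit$cb_names, fit$cb_names],
               vref[fit$cb_names, fit$cb_names], tolerance = 1e-5)
})

test_that("dispersion is calibrated on equi-dispersed data and scales the covariance", {
  st <- small_study(n_years = 6, seed = 29, overdispersion = 1)  # ~2100 obs
  cb <- crossbasis(st$exposure, spec = cb_spec())
  fit <- cc_fit(st$agg, cb)
  expect_gt(fit$dispersion, 0.9)
  expect_lt(fit$dispersion, 1.1)
  # vcov = phi * unscaled information inverse: Wald widths scale with sqrt(phi)
  expect_equal(fit$vcov, fit$dispersion * (fit$vcov / fit$dispersion))
  st2 <- small_study(n_years = 6, seed = 29, overdispersion = 2)
  fit2 <- cc_fit(aggregate_mortality(st2$mortality),
                 crossbasis(st2$exposure, spec = cb_spec()))
  expect_gt(fit2$dispersion, fit$dispersion)
})

test_that("per-stratum rate shifts are absorbed by the stratum terms, not beta", {
  # expected counts generated from the model family itself: fitting on them
  # recovers the generating coefficients, and shifting every stratum's
  # baseline moves only the stratum coefficients
  st <- small_study(n_years = 2, seed = 37)
  cb <- crossbasis(st$exposure, spec = cb_spec())
  d <- st$exposure$date
  strata <- make_strata(d)
  keep <- attr(cb, "valid")
  beta0 <- seq(-0.2, 0.2, length.out = 16)
  shifts <- seq(-0.3, 0.3, length.out = nlevels(strata))
  eta0 <- log(6) + drop(cb[keep, ] %*% beta0)
  mu1 <- mu2 <- rep(NA_real_, length(d))
  mu1[keep] <- exp(eta0)
  mu2[keep] <- exp(eta0 + shifts[as.integer(strata)[keep]])
  fit1 <- cc_fit(mu1, cb, dates = d, strata = strata, dow = FALSE)
  fit2 <- cc_fit(mu2, cb, dates = d, strata = strata, dow = FALSE)
  expect_lt(max(abs(coef(fit1)[fit1$cb_names] - beta0)), 1e-6)
  expect_lt(max(abs(coef(fit1)[fit1$cb_names] - coef(fit2)[fit2$cb_names])), 1e-6)
})

test_that("QAIC/QBIC follow their formulas and reduce to AIC at phi = 1", {
  ic <- quasi_ic(loglik = -100, dispersion = 1.5, k = 16, n = 2557)
  expect_equal(unname(ic["QAIC"]), 248)
  expect_equal(unname(ic["QBIC"]), 200 + log(2557) * 1.5 * 16)
  ic1 <- quasi_ic(-321.5, 1, k = 12, n = 500)
  expect_equal(unname(ic1["QAIC"]), -2 * -321.5 + 2 * 12)
  # QBIC exceeds QAIC whenever log(n) > 2
  expect_gt(quasi_ic(-10, 1.2, 4, 8)["QBIC"], quasi_ic(-10, 1.2, 4, 8)["QAIC"])
  expect_lt(quasi_ic(-10, 1.2, 4, 7)["QBIC"], quasi_ic(-10, 1.2, 4, 7)["QAIC"])
  st <- small_study(n_years = 2, seed = 3)
  fit <- cc_fit(st$agg, crossbasis(st$exposure, spec = cb_spec()))
  expect_equal(unname(information_criteria(fit)),
               unname(quasi_ic(fit$loglik, fit$dispersion, fit$k, fit$n)))
})

test_that("degenerate designs are rejected with informative errors", {
  x <- rep(20, 40) + rep(c(0, 1), 20)   # two-valued exposure
  spec <- cb_spec(max_lag = 2, var_df = 3, lag_df = 2,
                  var_knots = 20.5, var_boundary = c(19, 22))
  cb <- crossbasis(x, spec = spec)
  d <- as.Date("2004-01-01") + 0:39
  set.seed(8)
  y <- rpois(40, 5)
  expect_error(cc_fit(y, cb, dates = d, strata = make_strata(d)),
               "rank deficient|collinear")
})

test_that("strata with zero total count are dropped with a warning", {
  st <- small_study(n_years = 1, seed = 51)
  y <- st$agg$count
  strata <- make_strata(st$exposure$date)
  y[as.integer(strata) == 3] <- 0      # empty out one month
  cb <- crossbasis(st$exposure, spec = cb_spec())
  expect_warning(fit <- cc_fit(y, cb, dates = st$exposure$date, strata = strata),
                 "zero total count")
  expect_equal(fit$n_strata, nlevels(strata) - 1L)
})

test_that("df selection reports the full grid and degenerates to a singleton", {
  st <- small_study(n_years = 2, seed = 61)
  sel1 <- select_df(st$agg$count, st$exposure, var_df = 4, lag_df = 4)
  expect_equal(nrow(sel1$table), 1)
  expect_equal(sel1$spec$var_df, 4L)
  suppressMessages(
    sel <- select_df(st$agg$count, st$exposure, var_df = 4:6, lag_df = 4:6))
  expect_equal(nrow(sel$table), 9)
  expect_true(all(c("qaic", "qbic") %in% names(sel$table)))
  best <- sel$table[which.min(sel$table$qaic), ]
  expect_equal(c(sel$spec$var_df, sel$spec$lag_df),
               c(best$var_df, best$lag_df))
})

test_that("the time-series design uses 7 df/year and concurs with case-crossover", {
  st <- small_study(n_years = 1, seed = 71)
  cb <- crossbasis(st$exposure, spec = cb_spec())
  tfit <- ts_fit(st$agg$count, cb, dates = st$exposure$date)
  expect_equal(tfit$seasonal_df, 7L)
  # cross-design concordance on smooth seasonal data with a real effect
  surface <- rr_surface_spec("threshold_linear", 20, c(0.04, 0.02, rep(0, 9)))
  st2 <- small_study(n_years = 4, seed = 73, surface = surface)
  cb2 <- crossbasis(st2$exposure, spec = cb_spec())
  summ <- temperature_summary(st2$exposure)
  ccf <- cc_fit(st2$agg, cb2)
  tsf <- ts_fit(st2$agg$count, cb2, dates = st2$exposure$date)
  p_cc <- predict_rr(ccf, summ$p95, summ$reference)
  p_ts <- predict_rr(tsf, summ$p95, summ$reference)
  cc0 <- p_cc[p_cc$lag == 0, ]; ts0 <- p_ts[p_ts$lag == 0, ]
  expect_lt(max(cc0$lo, ts0$lo), min(cc0$hi, ts0$hi))  # overlapping 95% CIs
})

test_that("QAIC selection recovers the generating 4x4 df in most replicates", {
  hits <- 0; n_rep <- 20
  for (r in seq_len(n_rep)) {
    set.seed(200 + r)
    n <- 730
    x <- 19 + 8 * sin(2 * pi * seq_len(n) / 365 - pi / 2) + rnorm(n, 0, 1.8)
    d <- as.Date("2004-01-01") + seq_len(n) - 1
    cbm <- crossbasis(x, dates = d, spec = cb_spec(var_df = 4, lag_df = 4))
    beta0 <- runif(16, -0.04, 0.04)
    keep <- attr(cbm, "valid")
    mu <- rep(NA_real_, n)
    mu[keep] <- exp(log(5.4) + drop(cbm[keep, ] %*% beta0))
    y <- ifelse(is.na(mu), NA, rpois(n, ifelse(is.na(mu), 0, mu)))
    sel <- suppressMessages(suppressWarnings(select_df(y, x, dates = d)))
    if (all(sel$qaic_choice == c(4, 4))) hits <- hits + 1
  }
  expect_gt(hits, n_rep / 2)
})
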