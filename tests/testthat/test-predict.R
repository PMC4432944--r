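fit_small <- local({
  st <- small_study(n_years = 2, seed = 83)
  cb <- crossbasis(st$exposure, spec = cb_spec())
  list(fit = cc_fit(st$agg, cb), summary = temperature_summary(st$exposure),
       exposure = st$exposure)
})

test_that("RR is exactly 1 with a degenerate interval at the reference", {
  f <- fit_small$fit; s <- fit_small$summary
  surf <- predict_rr(f, c(s$reference, s$p95), s$reference)
  ref_rows <- surf[surf$temperature == s$reference, ]
  expect_identical(ref_rows$rr, rep(1, 11))
  expect_identical(ref_rows$lo, rep(1, 11))
  expect_identical(ref_rows$hi, rep(1, 11))
  cum <- cumulative_rr(f, s$reference, s$reference)
  expect_identical(cum$rr, 1)
  expect_identical(cum$lo, 1)
})

test_that("log RR matches the explicit contrast-vector computation", {
  f <- fit_small$fit; s <- fit_small$summary
  spec <- f$spec
  temps <- c(s$p90, s$p95, s$p99)
  surf <- predict_rr(f, temps, s$reference)
  beta <- coef(f)[f$cb_names]
  V <- vcov(f)[f$cb_names, f$cb_names]
  C <- lag_basis(spec)
  for (x in temps) for (l in c(0, 3, 10)) {
    bdiff <- drop(temperature_basis(x, spec) -
                  temperature_basis(s$reference, spec))
    w <- as.vector(t(outer(bdiff, C[l + 1, ])))  # (i outer, j inner) layout
    want <- sum(w * beta)
    got <- surf$logrr[surf$temperature == x & surf$lag == l]
    expect_lt(abs(got - want), 1e-12)
    se <- sqrt(drop(t(w) %*% V %*% w))
    expect_lt(abs(surf$se[surf$temperature == x & surf$lag == l] - se), 1e-12)
  }
})

test_that("cumulative RR equals the summed-contrast oracle and lag-0-only truth", {
  f <- fit_small$fit; s <- fit_small$summary
  spec <- f$spec
  beta <- coef(f)[f$cb_names]
  V <- vcov(f)[f$cb_names, f$cb_names]
  C <- lag_basis(spec)
  cum <- cumulative_rr(f, s$p95, s$reference)
  bdiff <- drop(temperature_basis(s$p95, spec) -
                temperature_basis(s$reference, spec))
  w <- Reduce(`+`, lapply(0:spec$max_lag,
                          function(l) as.vector(t(outer(bdiff, C[l + 1, ])))))
  expect_lt(abs(cum$logrr - sum(w * beta)), 1e-12)
  expect_lt(abs(cum$se - sqrt(drop(t(w) %*% V %*% w))), 1e-12)
  # summing the per-lag log RR gives the same point estimate
  surf <- predict_rr(f, s$p95, s$reference)
  expect_equal(cum$logrr, sum(surf$logrr), tolerance = 1e-12)
})

test_that("confidence bounds are the exponentiated log-scale bounds, ordered", {
  f <- fit_small$fit; s <- fit_small$summary
  surf <- predict_rr(f, rr_grid(f, s), s$reference)
  z <- qnorm(0.975)
  expect_identical(surf$lo, exp(surf$logrr - z * surf$se))
  expect_identical(surf$hi, exp(surf$logrr + z * surf$se))
  expect_true(all(surf$lo <= surf$rr & surf$rr <= surf$hi))
})

test_that("slices project surface cells exactly", {
  f <- fit_small$fit; s <- fit_small$summary
  grid <- rr_grid(f, s)
  surf <- predict_rr(f, grid, s$reference)
  ls <- lag_slice(surf, as.numeric(s$grid))
  expect_equal(nrow(ls), length(unique(as.numeric(s$grid))) * 11)
  for (r in sample(nrow(ls), 5)) {
    cell <- surf[surf$temperature == ls$temperature[r] & surf$lag == ls$lag[r], ]
    expect_identical(ls$rr[r], cell$rr)
  }
  ts <- temperature_slice(surf, c(0, 1, 2, 4))
  expect_setequal(unique(ts$lag), c(0, 1, 2, 4))
  # slices through the reference temperature pass through RR = 1
  surf2 <- predict_rr(f, c(s$reference, s$grid["p95"]), s$reference)
  ls2 <- lag_slice(surf2, s$reference)
  expect_identical(ls2$rr, rep(1, 11))
  expect_error(lag_slice(surf, -99), "not on the surface")
  expect_error(temperature_slice(surf, 99), "not on the surface")
})

test_that("prediction validates reference placement and fit consistency", {
  f <- fit_small$fit
  expect_error(predict_rr(f, 25, reference = -100), "outside")
  expect_error(predict_rr(f, 25, reference = c(1, 2)), "single")
})

test_that("a log-linear lag-0 effect is recovered within its confidence interval", {
  b <- 0.03
  hits0 <- 0; hits3 <- 0; n_rep <- 20
  for (r in seq_len(n_rep)) {
    surface <- rr_surface_spec("threshold_linear", 18, c(b, rep(0, 10)))
    st <- small_study(n_years = 4, seed = 100 + r, surface = surface)
    cb <- crossbasis(st$exposure, spec = cb_spec())
    fit <- cc_fit(st$agg, cb)
    s <- temperature_summary(st$exposure)
    surf <- predict_rr(fit, s$p95, s$reference)
    truth0 <- surface$eval(s$p95, 0) - surface$eval(s$reference, 0)
    r0 <- surf[surf$lag == 0, ]
    if (r0$lo <= exp(truth0) && exp(truth0) <= r0$hi) hits0 <- hits0 + 1
    r3 <- surf[surf$lag == 3, ]
    if (r3$lo <= 1 && 1 <= r3$hi) hits3 <- hits3 + 1
  }
  expect_gte(hits0, 0.9 * n_rep - 2)
  expect_gte(hits3, 0.9 * n_rep - 2)
})

test_that("plot methods draw without error on all three flavours", {
  f <- fit_small$fit; s <- fit_small$summary
  surf <- predict_rr(f, rr_grid(f, s), s$reference)
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  expect_no_error(plot(surf, "surface"))
  expect_no_error(plot(surf, "lag", at = as.numeric(s$grid)))
  expect_no_error(plot(surf, "temperature"))
  grDevices::dev.off()
  expect_true(file.exists(path))
})
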