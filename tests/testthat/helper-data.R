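# Small shared fixtures, built in code.

# toy exposure: seasonal-ish series, deterministic
toy_exposure <- function(n = 60, seed = 11) {
  set.seed(seed)
  20 + 6 * sin(2 * pi * seq_len(n) / 365) + rnorm(n, 0, 2)
}

# a small complete simulated study (counts aligned with exposure dates)
small_study <- function(n_years = 2, seed = 5, surface = NULL, overdispersion = 1.3) {
  cfg <- synthetic_config(
    n_years = n_years, n_stations = 3, seed = seed,
    true_surface = if (is.null(surface)) null_surface() else surface,
    overdispersion = overdispersion)
  st <- simulate_station_temperatures(cfg)
  w <- setNames(cfg$station_weights, sprintf("S%02d", seq_len(cfg$n_stations)))
  expo <- weighted_exposure(st, w, "mean")
  sim <- simulate_mortality(expo, cfg)
  agg <- aggregate_mortality(sim$mortality)
  list(config = cfg, exposure = expo, mortality = sim$mortality,
       agg = agg, truth = sim$truth)
}

# negative Poisson log-likelihood and gradient for the optimizer oracle
negll_poisson <- function(par, X, y) {
  eta <- drop(X %*% par)
  sum(exp(eta)) - sum(y * eta)
}
negll_grad <- function(par, X, y) {
  mu <- exp(drop(X %*% par))
  drop(t(X) %*% (mu - y))
}

# design matrix mirroring the fit's layout, built independently in the test
build_design <- function(cb, dates, strata, dow = TRUE) {
  keep <- attr(cb, "valid")
  X <- cbind(1, cb[keep, , drop = FALSE])
  sf <- factor(strata[keep])
  if (nlevels(sf) > 1) X <- cbind(X, model.matrix(~sf)[, -1, drop = FALSE])
  if (dow) {
    dw <- heatlag:::dow_factor(dates[keep])
    X <- cbind(X, model.matrix(~dw)[, -1, drop = FALSE])
  }
  list(X = X, keep = keep)
}
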