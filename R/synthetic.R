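## Synthetic study generator: station temperatures and cause-specific daily
## mortality counts with the statistical structure the case-crossover DLNM
## analysis assumes, plus the full ground truth needed for recovery tests.

# Evaluate-and-restore seeding so generator calls are deterministic without
# clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# ICD-10 circulatory-disease groups used throughout: hypertensive, ischaemic
# heart, other heart, cerebrovascular, remainder of circulatory system.
icd10_categories <- c("I10-I13", "I20-I25", "I26-I51", "I60-I69", "I71-I99")

# Registry-scale defaults: 7-year national cause-of-death totals for the five
# groups (Cyprus, 2004-2010 scale), used to apportion simulated deaths.
default_category_totals <- c("I10-I13" = 1220, "I20-I25" = 4773,
                             "I26-I51" = 4595, "I60-I69" = 2893,
                             "I71-I99" = 408)

#' Known exposure-lag-response surface for simulation
#'
#' Specifies the true log relative-risk surface `f(x, l)` injected into
#' simulated mortality. Both available shapes are exactly zero at (and below)
#' the reference temperature for every lag, mirroring a heat effect:
#' `"threshold_linear"` is `coef[l+1] * max(0, x - reference)` (log-RR per
#' degree C above reference) and `"quadratic_above_reference"` replaces the
#' linear excess with its square.
#'
#' @param form surface shape.
#' @param reference reference temperature in degrees C.
#' @param lag_coef numeric vector of per-lag coefficients for lags
#'   `0..length(lag_coef)-1`.
#' @return object of class `"rr_surface_spec"` with an `eval(x, lag)` closure.
#' @examples
#' # effect confined to lags 0-1: +3%/degC on the day, +1%/degC the day after
#' s <- rr_surface_spec("threshold_linear", reference = 20,
#'                      lag_coef = c(0.03, 0.01, rep(0, 9)))
#' s$eval(25, 0)   # log RR at 25 degC, lag 0
#' @export
rr_surface_spec <- function(form = c("threshold_linear", "quadratic_above_reference"),
                            reference, lag_coef) {
  form <- match.arg(form)
  stopifnot(is.numeric(reference), length(reference) == 1,
            is.numeric(lag_coef), length(lag_coef) >= 1)
  shape <- switch(form,
    threshold_linear = function(x) pmax(0, x - reference),
    quadratic_above_reference = function(x) pmax(0, x - reference)^2)
  out <- list(form = form, reference = reference, lag_coef = lag_coef,
              max_lag = length(lag_coef) - 1L,
              eval = function(x, lag) lag_coef[lag + 1L] * shape(x))
  class(out) <- "rr_surface_spec"
  out
}

#' A null (all-zero) true surface
#' @param max_lag maximum lag of the zero surface.
#' @param reference reference temperature in degrees C.
#' @return an [rr_surface_spec()] that evaluates to 0 everywhere.
#' @export
null_surface <- function(max_lag = 10L, reference = 20)
  rr_surface_spec("threshold_linear", reference, rep(0, max_lag + 1L))

#' Configuration of the synthetic study generator
#'
#' Bundles the climate, population and mortality parameters of one simulated
#' study. Defaults emulate a subtropical Mediterranean island over seven
#' years: daily mean temperatures averaging about 26-27 degC in summer and
#' 8-11 degC in winter, five ICD-10 circulatory-disease categories totalling
#' roughly 13,900 deaths over 2,555 days (about 5.4/day), winter-peaking
#' seasonality, small day-of-week reporting effects, and mild overdispersion.
#'
#' Simulated years have 365 days (no leap days); real-data ingestion accepts
#' true calendars.
#'
#' @param n_years number of simulated years (365 days each).
#' @param n_stations number of weather stations.
#' @param station_weights non-negative station weights (default: equal).
#' @param climate_mean_annual annual mean of the area temperature, degC.
#' @param climate_seasonal_amplitude half-range of the seasonal cycle, degC.
#' @param climate_daily_noise_sd sd of day-to-day weather noise, degC.
#' @param station_offset_sd sd of time-constant station offsets (altitude
#'   etc.), degC.
#' @param diurnal_range mean day/night excursion of `t_max`/`t_min` around
#'   `t_mean`, degC.
#' @param baseline_daily_deaths expected aggregate deaths per day at the
#'   reference temperature on the reference weekday.
#' @param dow_log_effects 7 log-rate offsets, Monday first.
#' @param seasonal_log_amplitude amplitude of the winter-peaking log-rate
#'   seasonal cycle.
#' @param category_shares expected share of each ICD-10 category; default
#'   proportional to registry-scale totals.
#' @param true_surface an [rr_surface_spec()]; default null.
#' @param overdispersion variance inflation factor phi >= 1 of daily counts.
#' @param start_date first calendar date of the simulation.
#' @param seed integer seed; every generator draw flows through it.
#' @return object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_years = 7L, n_stations = 5L,
                             station_weights = NULL,
                             climate_mean_annual = 19,
                             climate_seasonal_amplitude = 8,
                             climate_daily_noise_sd = 1.8,
                             station_offset_sd = 1,
                             diurnal_range = 5,
                             baseline_daily_deaths = 13889 / 2555,
                             dow_log_effects = c(0.02, 0, 0, 0, 0.01, -0.02, -0.03),
                             seasonal_log_amplitude = 0.15,
                             category_shares = default_category_totals /
                               sum(default_category_totals),
                             true_surface = null_surface(),
                             overdispersion = 1.3,
                             start_date = as.Date("2004-01-01"),
                             seed = 1L) {
  if (!is_count(n_years) || n_years < 1) stop2("n_years must be an integer >= 1")
  if (!is_count(n_stations) || n_stations < 1) stop2("n_stations must be >= 1")
  if (is.null(station_weights)) station_weights <- rep(1, n_stations)
  if (length(station_weights) != n_stations)
    stop2("station_weights length (%d) must equal n_stations (%d)",
          length(station_weights), n_stations)
  if (any(station_weights < 0) || all(station_weights == 0))
    stop2("station weights must be non-negative with at least one positive")
  for (nm in c("climate_seasonal_amplitude", "climate_daily_noise_sd",
               "station_offset_sd", "diurnal_range", "seasonal_log_amplitude"))
    if (get(nm) < 0) stop2("%s must be non-negative", nm)
  if (length(dow_log_effects) != 7) stop2("dow_log_effects must have length 7")
  if (overdispersion < 1) stop2("overdispersion must be >= 1")
  if (baseline_daily_deaths <= 0) stop2("baseline_daily_deaths must be positive")
  if (!inherits(true_surface, "rr_surface_spec"))
    stop2("true_surface must be an rr_surface_spec")
  category_shares <- category_shares / sum(category_shares)
  structure(list(n_years = as.integer(n_years),
                 n_stations = as.integer(n_stations),
                 station_weights = station_weights,
                 climate_mean_annual = climate_mean_annual,
                 climate_seasonal_amplitude = climate_seasonal_amplitude,
                 climate_daily_noise_sd = climate_daily_noise_sd,
                 station_offset_sd = station_offset_sd,
                 diurnal_range = diurnal_range,
                 baseline_daily_deaths = baseline_daily_deaths,
                 dow_log_effects = dow_log_effects,
                 seasonal_log_amplitude = seasonal_log_amplitude,
                 category_shares = category_shares,
                 true_surface = true_surface,
                 overdispersion = overdispersion,
                 start_date = as.Date(start_date),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Seasonal temperature cycle: peaks mid-year (day ~183), so `sin` phase -pi/2.
season_temp <- function(doy) sin(2 * pi * doy / 365 - pi / 2)
# Mortality seasonality peaks in winter (day-of-year ~ 1/365).
season_mort <- function(doy) cos(2 * pi * doy / 365)

sim_dates <- function(config)
  seq(config$start_date, by = "day", length.out = config$n_years * 365L)

#' Simulate multi-station daily temperature records
#'
#' Each station's daily mean is the sum of the area annual mean, a sinusoidal
#' seasonal cycle peaking mid-year, a time-constant station offset and iid
#' daily noise; `t_max`/`t_min` add/subtract a non-negative diurnal
#' excursion, so `t_min <= t_mean <= t_max` holds on every record.
#'
#' @param config a [synthetic_config()].
#' @return data frame with columns `station_id`, `date`, `t_min`, `t_max`,
#'   `t_mean`; deterministic given `config$seed`.
#' @export
simulate_station_temperatures <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    dates <- sim_dates(config)
    nd <- length(dates)
    doy <- ((seq_len(nd) - 1L) %% 365L) + 1L
    base <- config$climate_mean_annual +
      config$climate_seasonal_amplitude * season_temp(doy)
    offs <- stats::rnorm(config$n_stations, 0, config$station_offset_sd)
    recs <- lapply(seq_len(config$n_stations), function(s) {
      tm <- base + offs[s] + stats::rnorm(nd, 0, config$climate_daily_noise_sd)
      up <- pmax(0, stats::rnorm(nd, config$diurnal_range, 1))
      dn <- pmax(0, stats::rnorm(nd, config$diurnal_range, 1))
      data.frame(station_id = sprintf("S%02d", s), date = dates,
                 t_min = tm - dn, t_max = tm + up, t_mean = tm)
    })
    do.call(rbind, recs)
  })
}

#' Simulate daily cause-specific mortality counts with known truth
#'
#' Draws daily aggregate deaths from a (possibly overdispersed) Poisson model
#' whose log mean is the sum of a baseline, a winter-peaking seasonal cycle,
#' day-of-week offsets and the injected exposure-lag-response surface summed
#' over the lagged temperature history. Overdispersed draws use a negative
#' binomial parameterized so that the variance equals
#' `overdispersion * mu`. Aggregate counts are apportioned across the five
#' ICD-10 categories by multinomial thinning, which preserves the Poisson
#' structure per category.
#'
#' The first `max_lag` days are generated with truncated lag history and
#' flagged (`warmup`) so fitting can exclude them.
#'
#' @param exposure an exposure series from [weighted_exposure()] or a numeric
#'   vector of daily temperatures (one per consecutive day).
#' @param config a [synthetic_config()].
#' @return list with `mortality` (long data frame `date`, `category`,
#'   `count`) and `truth` (class `"synthetic_truth"`: realized `mu`,
#'   aggregate counts, the surface spec, warm-up flags, seed).
#' @export
simulate_mortality <- function(exposure, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.data.frame(exposure)) {
    dates <- as.Date(exposure$date); x <- exposure$temp
  } else {
    x <- as.numeric(exposure)
    dates <- seq(config$start_date, by = "day", length.out = length(x))
  }
  surf <- config$true_surface
  L <- surf$max_lag
  n <- length(x)
  if (n < L + 1) stop2("exposure must cover at least max_lag + 1 = %d days", L + 1)
  if (anyNA(x)) stop2("exposure series has missing values; impute or trim first")
  # lagged surface contribution, truncated history on the first L days
  fx <- vapply(0:L, function(l) surf$eval(x, l), numeric(n))  # n x (L+1)
  eff <- numeric(n)
  for (l in 0:L) {
    idx <- (l + 1):n
    eff[idx] <- eff[idx] + fx[idx - l, l + 1L]
  }
  doy <- ((seq_len(n) - 1L) %% 365L) + 1L
  eta <- log(config$baseline_daily_deaths) +
    config$seasonal_log_amplitude * season_mort(doy) +
    config$dow_log_effects[as.integer(dow_factor(dates))] + eff
  mu <- exp(eta)
  with_seed(config$seed + 1L, {
    y <- if (config$overdispersion == 1) stats::rpois(n, mu)
         else stats::rnbinom(n, mu = mu, size = mu / (config$overdispersion - 1))
    # apportion each day's aggregate count across categories
    cat_counts <- vapply(seq_len(n), function(i) {
      if (y[i] == 0) integer(length(config$category_shares))
      else as.integer(stats::rmultinom(1, y[i], config$category_shares))
    }, integer(length(config$category_shares)))
  })
  mortality <- data.frame(
    date = rep(dates, each = length(icd10_categories)),
    category = rep(icd10_categories, n),
    count = as.integer(cat_counts))
  truth <- structure(list(dates = dates, exposure = x, mu = mu, counts = y,
                          surface = surf,
                          warmup = seq_len(n) <= L, seed = config$seed),
                     class = "synthetic_truth")
  list(mortality = mortality, truth = truth)
}

#' Aggregate a long cause-specific mortality table to daily totals
#'
#' @param mortality long data frame with `date`, `category`, `count`.
#' @param categories categories to sum (default all present).
#' @return data frame `date`, `count` sorted by date.
#' @export
aggregate_mortality <- function(mortality, categories = NULL) {
  if (!all(c("date", "category", "count") %in% names(mortality)))
    stop2("mortality table needs columns date, category, count")
  if (!is.null(categories)) mortality <- mortality[mortality$category %in% categories, ]
  agg <- stats::aggregate(count ~ date, mortality, sum)
  agg$date <- as.Date(agg$date)
  agg[order(agg$date), ]
}

#' Write a complete synthetic study to disk
#'
#' Emits the three standard input tables (tab-separated, ISO-8601 dates,
#' header row) plus a key-value truth file recording the generator
#' parameters and seed.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of file paths written.
#' @export
write_synthetic_study <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stations <- simulate_station_temperatures(config)
  w <- stats::setNames(config$station_weights,
                       sprintf("S%02d", seq_len(config$n_stations)))
  expo <- weighted_exposure(stations, w, "mean")
  sim <- simulate_mortality(expo, config)
  paths <- list(
    stations = file.path(dir, "stations.tsv"),
    weights = file.path(dir, "weights.tsv"),
    mortality = file.path(dir, "mortality.tsv"),
    truth = file.path(dir, "truth.txt"))
  utils::write.table(stations, paths$stations, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(station_id = names(w), weight = unname(w)),
                     paths$weights, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(sim$mortality, paths$mortality, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  tr <- c(seed = config$seed, n_years = config$n_years,
          baseline_daily_deaths = config$baseline_daily_deaths,
          overdispersion = config$overdispersion,
          surface_form = config$true_surface$form,
          surface_reference = config$true_surface$reference,
          surface_lag_coef = paste(config$true_surface$lag_coef, collapse = ","),
          dow_log_effects = paste(config$dow_log_effects, collapse = ","),
          seasonal_log_amplitude = config$seasonal_log_amplitude)
  writeLines(paste(names(tr), tr, sep = "="), paths$truth)
  invisible(paths)
}
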