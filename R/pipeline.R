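#' Configuration of a full study run
#'
#' Bundles every choice of a complete analysis: where the three input tables
#' live (or a [synthetic_config()] to generate them), which temperature
#' metrics and mortality categories to analyze, the cross-basis defaults,
#' the stratification scheme, the degrees-of-freedom selection grid and the
#' sensitivity-analysis variants.
#'
#' @param stations_path,weights_path,mortality_path input table paths;
#'   ignored when `synthetic` is given.
#' @param synthetic optional [synthetic_config()]; when present the inputs
#'   are generated (and written to `out_dir/inputs/`).
#' @param metrics temperature metrics to analyze.
#' @param categories ICD-10 category codes to fit individually.
#' @param aggregate also fit the category-summed series.
#' @param max_lag,var_df,lag_df,lag_knot_spacing cross-basis defaults, see
#'   [cb_spec()].
#' @param strata_scheme `"calendar_month"` or `"fixed_window"`.
#' @param window stratum window length for `"fixed_window"`.
#' @param run_df_selection fit the `{4,5,6} x {4,5,6}` df grid on the
#'   aggregated series of the first metric.
#' @param df_grid list with integer vectors `var_df`, `lag_df`.
#' @param sensitivity list with `max_lags` and `windows` (window lengths in
#'   days; `NA` denotes the calendar-month base scheme).
#' @param run_sensitivity run the sensitivity refits during [run_study()].
#' @param out_dir artifact directory.
#' @param seed integer seed for anything stochastic downstream.
#' @return list of class `"analysis_config"`.
#' @export
analysis_config <- function(stations_path = NULL, weights_path = NULL,
                            mortality_path = NULL, synthetic = NULL,
                            metrics = c("mean", "max", "min"),
                            categories = icd10_categories, aggregate = TRUE,
                            max_lag = 10L, var_df = 4L, lag_df = 4L,
                            lag_knot_spacing = "linear",
                            strata_scheme = "calendar_month", window = NULL,
                            run_df_selection = TRUE,
                            df_grid = list(var_df = 4:6, lag_df = 4:6),
                            sensitivity = list(max_lags = c(5L, 15L, 20L),
                                               windows = c(30L, 28L, 21L)),
                            run_sensitivity = TRUE,
                            out_dir = "heatlag-artifacts", seed = 1L) {
  if (is.null(synthetic) &&
      (is.null(stations_path) || is.null(weights_path) || is.null(mortality_path)))
    stop2("either the three input paths or a synthetic block must be given")
  if (!length(metrics)) stop2("metrics must be non-empty")
  metrics <- match.arg(metrics, c("mean", "max", "min"), several.ok = TRUE)
  if (!is.null(sensitivity$max_lags) && any(sensitivity$max_lags < 1))
    stop2("sensitivity max_lags must all be >= 1")
  structure(list(stations_path = stations_path, weights_path = weights_path,
                 mortality_path = mortality_path, synthetic = synthetic,
                 metrics = metrics, categories = categories,
                 aggregate = aggregate, max_lag = as.integer(max_lag),
                 var_df = as.integer(var_df), lag_df = as.integer(lag_df),
                 lag_knot_spacing = lag_knot_spacing,
                 strata_scheme = strata_scheme, window = window,
                 run_df_selection = run_df_selection, df_grid = df_grid,
                 sensitivity = sensitivity, run_sensitivity = run_sensitivity,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML document
#'
#' Keys mirror the arguments of [analysis_config()]; a `synthetic:` block
#' (keys mirroring [synthetic_config()], with `surface_form`,
#' `surface_reference`, `surface_lag_coef` describing the true surface) is
#' converted to a [synthetic_config()].
#'
#' @param path YAML file.
#' @return an `"analysis_config"`.
#' @export
read_analysis_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop2("the 'yaml' package is needed to read YAML configurations")
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$synthetic)) {
    sb <- cfg$synthetic
    surf <- if (!is.null(sb$surface_lag_coef))
      rr_surface_spec(sb$surface_form %||% "threshold_linear",
                      sb$surface_reference %||% 20,
                      as.numeric(sb$surface_lag_coef))
      else NULL
    sb[c("surface_form", "surface_reference", "surface_lag_coef")] <- NULL
    if (!is.null(surf)) sb$true_surface <- surf
    cfg$synthetic <- do.call(synthetic_config, sb)
  }
  do.call(analysis_config, cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

study_strata <- function(dates, config) {
  if (identical(config$strata_scheme, "calendar_month")) make_strata(dates)
  else make_strata(dates, "fixed_window", window = config$window)
}

log_line <- function(log, fmt, ...) c(log, sprintf(fmt, ...))

#' Run the full temperature-mortality study
#'
#' End-to-end orchestration: ingest (or synthesize) the inputs, build the
#' population-weighted exposure series per temperature metric, summarize the
#' temperature distribution, fit the aggregated and per-category
#' case-crossover models, predict relative-risk surfaces and their lag /
#' temperature slices, optionally run degrees-of-freedom selection and the
#' sensitivity analysis, and write every artifact (tab-separated text) plus
#' a run log of all resolved defaults under `config$out_dir`.
#'
#' Deterministic given `config` and its seed.
#'
#' @param config an [analysis_config()].
#' @return invisibly, a list with the in-memory artifacts: per-metric
#'   `exposure`, `summary`, `fits`, `surfaces`, `slices`; plus `df_selection`
#'   and `sensitivity` when enabled.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  log <- log_line(log, "seed=%d", config$seed)

  if (!is.null(config$synthetic)) {
    idir <- file.path(out, "inputs")
    paths <- write_synthetic_study(config$synthetic, idir)
    config$stations_path <- paths$stations
    config$weights_path <- paths$weights
    config$mortality_path <- paths$mortality
    log <- log_line(log, "inputs=synthetic dir=%s generator_seed=%d", idir,
                    config$synthetic$seed)
  }
  inp <- ingest_tables(config$stations_path, config$weights_path,
                       config$mortality_path)
  # count conservation across categories is checked on the aggregate
  agg <- aggregate_mortality(inp$mortality)
  per_cat <- split(inp$mortality, inp$mortality$category)
  chk <- Reduce(`+`, lapply(per_cat, function(d) d$count[order(d$date)]))
  if (length(chk) == nrow(agg) && !all(chk == agg$count))
    stop2("aggregate mortality does not equal the category sum; refusing to continue")

  log <- log_line(log, "strata=%s%s", config$strata_scheme,
                  if (is.null(config$window)) "" else sprintf(":%d", config$window))
  log <- log_line(log, "crossbasis max_lag=%d var_df=%d (degree 2) lag_df=%d lag_knot_spacing=%s lag_intercept=TRUE",
                  config$max_lag, config$var_df, config$lag_df,
                  config$lag_knot_spacing)
  log <- log_line(log, "dispersion=pearson dow_reference=Monday warmup_excluded=%d percentile_type=7",
                  config$max_lag)

  results <- list()
  series_list <- if (config$aggregate) c(list(aggregated = agg),
                     lapply(per_cat, function(d) d[order(d$date), c("date", "count")]))
                 else lapply(per_cat, function(d) d[order(d$date), c("date", "count")])

  for (metric in config$metrics) {
    expo <- weighted_exposure(inp$stations, inp$weights, metric)
    summ <- temperature_summary(expo)
    mdir <- file.path(out, paste0("t_", metric))
    dir.create(mdir, showWarnings = FALSE)
    write_exposure(expo, file.path(mdir, "exposure.tsv"))
    write_exposure(summ, file.path(mdir, "temperature_summary.tsv"))
    spec <- cb_spec(max_lag = config$max_lag, var_df = config$var_df,
                    lag_df = config$lag_df,
                    lag_knot_spacing = config$lag_knot_spacing)
    cbm <- crossbasis(expo, spec = spec)
    strata <- study_strata(expo$date, config)
    fits <- list(); surfaces <- list(); slices <- list()
    for (nm in names(series_list)) {
      y <- series_list[[nm]]
      # align counts to the exposure calendar
      yv <- y$count[match(expo$date, as.Date(y$date))]
      fit <- cc_fit(yv, cbm, dates = expo$date, strata = strata)
      fits[[nm]] <- fit
      write_fit(fit, file.path(mdir, sprintf("fit_%s.tsv", gsub("[^A-Za-z0-9]", "_", nm))))
      surf <- predict_rr(fit, rr_grid(fit, summ), reference = summ$reference)
      surfaces[[nm]] <- surf
      write_rr_table(surf, file.path(mdir, sprintf("rr_surface_%s.tsv",
                                                   gsub("[^A-Za-z0-9]", "_", nm))))
      if (nm == "aggregated") {
        slices$lag <- lag_slice(surf, as.numeric(summ$grid))
        slices$temperature <- temperature_slice(surf, intersect(c(0, 1, 2, 4), surf$lag))
        slices$cumulative <- cumulative_rr(fit, as.numeric(summ$grid), summ$reference)
        write_rr_table(slices$lag, file.path(mdir, "lag_slices.tsv"))
        write_rr_table(slices$temperature, file.path(mdir, "temperature_slices.tsv"))
        write_rr_table(slices$cumulative, file.path(mdir, "cumulative_rr.tsv"))
        grDevices::png(file.path(mdir, "rr_surface.png"), 900, 700)
        plot(surf, "surface"); grDevices::dev.off()
        grDevices::png(file.path(mdir, "lag_slices.png"), 900, 700)
        plot(surf, "lag", at = as.numeric(summ$grid)); grDevices::dev.off()
        grDevices::png(file.path(mdir, "temperature_slices.png"), 900, 700)
        plot(surf, "temperature"); grDevices::dev.off()
      }
      log <- log_line(log, "fit metric=%s series=%s n=%d k=%d phi=%.4f qaic=%.2f",
                      metric, nm, fit$n, fit$k, fit$dispersion, fit$qaic)
    }
    results[[paste0("t_", metric)]] <-
      list(exposure = expo, summary = summ, fits = fits, surfaces = surfaces,
           slices = slices)
  }

  first <- results[[paste0("t_", config$metrics[1])]]
  if (config$run_df_selection) {
    sel <- select_df(series_list[[1]]$count[match(first$exposure$date,
                                                  as.Date(series_list[[1]]$date))],
                     first$exposure, var_df = config$df_grid$var_df,
                     lag_df = config$df_grid$lag_df, max_lag = config$max_lag,
                     strata = study_strata(first$exposure$date, config),
                     lag_knot_spacing = config$lag_knot_spacing)
    utils::write.table(sel$table, file.path(out, "df_selection.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    results$df_selection <- sel
    log <- log_line(log, "df_selection var_df=%d lag_df=%d",
                    sel$qaic_choice[1], sel$qaic_choice[2])
  }
  if (config$run_sensitivity) {
    sens <- run_sensitivity(config, inputs = inp)
    utils::write.table(sens, file.path(out, "sensitivity.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    results$sensitivity <- sens
    log <- log_line(log, "sensitivity variants=%d", nrow(sens))
  }
  writeLines(log, file.path(out, "run_log.txt"))
  invisible(results)
}

#' Sensitivity analysis over maximum lag and stratum window
#'
#' Refits the aggregated case-crossover model of the first configured
#' metric, varying one factor at a time (as is standard): the maximum lag
#' over `config$sensitivity$max_lags` and the stratum scheme over
#' fixed windows of `config$sensitivity$windows` days, each compared with
#' the base configuration. For every variant the relative risk and 95% CI
#' at the integer 90th/95th/99th-percentile temperatures are tabulated at
#' lag 0 and cumulated over lags; `outside_base_ci` flags variants whose
#' point estimate at p95/lag 0 leaves the base fit's confidence interval.
#' Variant failures are recorded and the run continues.
#'
#' @param config an [analysis_config()].
#' @param inputs optional pre-ingested tables (as from [ingest_tables()]).
#' @return data frame of class `"sensitivity_report"`, one row per
#'   (variant, evaluation temperature).
#' @export
run_sensitivity <- function(config, inputs = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(inputs)) {
    if (!is.null(config$synthetic)) {
      idir <- file.path(config$out_dir, "inputs")
      if (!file.exists(file.path(idir, "stations.tsv")))
        write_synthetic_study(config$synthetic, idir)
      inputs <- ingest_tables(file.path(idir, "stations.tsv"),
                              file.path(idir, "weights.tsv"),
                              file.path(idir, "mortality.tsv"))
    } else {
      inputs <- ingest_tables(config$stations_path, config$weights_path,
                              config$mortality_path)
    }
  }
  metric <- config$metrics[1]
  expo <- weighted_exposure(inputs$stations, inputs$weights, metric)
  summ <- temperature_summary(expo)
  agg <- aggregate_mortality(inputs$mortality)
  yv <- agg$count[match(expo$date, agg$date)]
  temps <- as.numeric(summ$grid[c("p90", "p95", "p99")])

  variants <- data.frame(variant = "base", max_lag = config$max_lag,
                         window = NA_integer_)
  for (L in setdiff(config$sensitivity$max_lags, config$max_lag))
    variants <- rbind(variants, data.frame(
      variant = sprintf("max_lag_%d", L), max_lag = L, window = NA_integer_))
  for (w in config$sensitivity$windows)
    variants <- rbind(variants, data.frame(
      variant = sprintf("window_%d", w), max_lag = config$max_lag, window = w))

  one <- function(L, w) {
    spec <- cb_spec(max_lag = L, var_df = config$var_df,
                    lag_df = config$lag_df,
                    lag_knot_spacing = config$lag_knot_spacing)
    cbm <- crossbasis(expo, spec = spec)
    strata <- if (is.na(w)) make_strata(expo$date)
              else make_strata(expo$date, "fixed_window", window = w)
    fit <- cc_fit(yv, cbm, dates = expo$date, strata = strata)
    lag0 <- predict_rr(fit, temps, summ$reference)
    lag0 <- lag0[lag0$lag == 0, ]
    cum <- cumulative_rr(fit, temps, summ$reference)
    data.frame(percentile = c("p90", "p95", "p99"),
               temperature = temps,
               rr_lag0 = lag0$rr, lo_lag0 = lag0$lo, hi_lag0 = lag0$hi,
               rr_cum = cum$rr, lo_cum = cum$lo, hi_cum = cum$hi)
  }

  rows <- list(); base_tab <- NULL
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    tab <- tryCatch(one(v$max_lag, v$window), error = function(e) {
      warn2("sensitivity variant %s failed: %s", v$variant, conditionMessage(e))
      NULL
    })
    if (is.null(tab)) {
      rows[[i]] <- data.frame(variant = v$variant, percentile = NA,
                              temperature = NA, rr_lag0 = NA, lo_lag0 = NA,
                              hi_lag0 = NA, rr_cum = NA, lo_cum = NA,
                              hi_cum = NA, delta_rr_lag0 = NA,
                              outside_base_ci = NA, failed = TRUE)
      next
    }
    if (v$variant == "base") base_tab <- tab
    rows[[i]] <- cbind(variant = v$variant, tab,
                       delta_rr_lag0 = tab$rr_lag0 - base_tab$rr_lag0,
                       outside_base_ci = tab$rr_lag0 < base_tab$lo_lag0 |
                         tab$rr_lag0 > base_tab$hi_lag0,
                       failed = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sensitivity_report", "data.frame")
  out
}
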