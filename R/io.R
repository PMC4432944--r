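## Ingestion of the three standard input tables: station temperatures,
## station population weights, daily cause-specific mortality counts.
## Dialect: delimiter-separated text (tab or comma, sniffed from the header
## line), header row, ISO-8601 dates.

read_table_auto <- function(path) {
  if (!file.exists(path)) stop2("input file not found: %s", path)
  hdr <- readLines(path, n = 1)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop2("%s table is missing required column(s): %s",
                          what, paste(miss, collapse = ", "))
}

# Parse dates, reporting a count and the first few offending raw values.
parse_dates <- function(x, what) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- is.na(d) & !is.na(x)
  if (any(bad)) {
    warn2("%s: %d unparseable date(s), e.g. %s; rows dropped", what, sum(bad),
          paste(utils::head(unique(x[bad]), 10), collapse = ", "))
  }
  d
}

#' Read and validate the three study input tables
#'
#' Station records must carry `station_id`, `date` and at least one of
#' `t_mean`, `t_max`, `t_min`; rows violating `t_min <= t_mean <= t_max` are
#' rejected with a warning and the run proceeds. Weights need `station_id`
#' and `weight` (non-negative, at least one positive). Mortality needs
#' `date`, `category`, `count` with non-negative integer counts; an empty
#' table is a hard error.
#'
#' @param stations_path,weights_path,mortality_path file paths.
#' @return list with validated data frames `stations`, `weights`,
#'   `mortality`.
#' @export
ingest_tables <- function(stations_path, weights_path, mortality_path) {
  st <- read_table_auto(stations_path)
  require_cols(st, c("station_id", "date"), "station")
  if (!any(c("t_mean", "t_max", "t_min") %in% names(st)))
    stop2("station table has none of t_mean, t_max, t_min")
  st$date <- parse_dates(st$date, "station table")
  st <- st[!is.na(st$date), ]
  if (anyDuplicated(st[c("station_id", "date")]))
    stop2("duplicate (station_id, date) rows in station table")
  if (all(c("t_min", "t_max", "t_mean") %in% names(st))) {
    bad <- with(st, !is.na(t_min) & !is.na(t_max) & !is.na(t_mean) &
                  !(t_min <= t_mean & t_mean <= t_max))
    if (any(bad)) {
      warn2("station table: %d row(s) violate t_min <= t_mean <= t_max; rejected (first: %s %s)",
            sum(bad), st$station_id[which(bad)[1]],
            format(st$date[which(bad)[1]]))
      st <- st[!bad, ]
    }
  }

  wt <- read_table_auto(weights_path)
  require_cols(wt, c("station_id", "weight"), "weights")
  if (anyNA(wt$weight) || any(wt$weight < 0) || !any(wt$weight > 0))
    stop2("weights must be non-negative with at least one positive entry")

  mo <- read_table_auto(mortality_path)
  require_cols(mo, c("date", "category", "count"), "mortality")
  if (!nrow(mo)) stop2("mortality table is empty")
  mo$date <- parse_dates(mo$date, "mortality table")
  mo <- mo[!is.na(mo$date), ]
  if (!nrow(mo)) stop2("mortality table has no parseable rows")
  if (anyNA(mo$count) || any(mo$count < 0) || any(mo$count != round(mo$count)))
    stop2("mortality counts must be non-negative integers")
  mo$count <- as.integer(mo$count)

  list(stations = st, weights = wt, mortality = mo)
}

#' Write an exposure series or temperature summary as text
#'
#' @param x an `"exposure_series"` data frame or `"temperature_summary"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_exposure <- function(x, path) {
  if (inherits(x, "temperature_summary")) {
    df <- data.frame(quantity = c("reference", "p90", "p95", "p99",
                                  "upper_limit", "grid_p90", "grid_p95",
                                  "grid_p99", "grid_max"),
                     value = c(x$reference, x$p90, x$p95, x$p99,
                               x$upper_limit, x$grid))
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Serialize a fitted model as a text artifact
#'
#' Coefficients, covariance and fit metadata in a single tab-separated file,
#' sufficient to recompute relative-risk surfaces without refitting.
#'
#' @param fit a `"cc_fit"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  con <- file(path, "w"); on.exit(close(con))
  s <- fit$spec
  meta <- c(design = fit$design, n = fit$n, k = fit$k,
            dispersion = format(fit$dispersion, digits = 17),
            loglik = format(fit$loglik, digits = 17),
            qaic = format(fit$qaic, digits = 17),
            qbic = format(fit$qbic, digits = 17),
            max_lag = s$max_lag, var_df = s$var_df, lag_df = s$lag_df,
            var_knots = paste(format(s$var_knots, digits = 17), collapse = ","),
            var_boundary = paste(format(s$var_boundary, digits = 17), collapse = ","))
  writeLines(paste0("# ", names(meta), "=", meta), con)
  co <- data.frame(term = names(fit$coefficients),
                   estimate = unname(fit$coefficients))
  utils::write.table(co, con, sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines("# vcov (cross-basis block)", con)
  utils::write.table(as.data.frame(cb_vcov(fit)), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
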