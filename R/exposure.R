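#' Normalize station population weights
#'
#' Divides raw station populations (or any non-negative weights) by their sum
#' so the weights sum to one. Spatial averaging by population weight assumes
#' mortality is proportional to population size, so only relative weights
#' matter.
#'
#' @param raw named numeric vector, `station_id -> weight`, or a data frame
#'   with columns `station_id` and `weight`.
#' @return named numeric vector summing to 1.
#' @examples
#' normalize_weights(c(A = 2, B = 2))
#' @export
normalize_weights <- function(raw) {
  if (is.data.frame(raw)) {
    if (!all(c("station_id", "weight") %in% names(raw)))
      stop2("weights table needs columns 'station_id' and 'weight'")
    raw <- stats::setNames(as.numeric(raw$weight), as.character(raw$station_id))
  }
  if (!length(raw)) stop2("no weights supplied")
  if (anyNA(raw) || any(raw < 0)) stop2("weights must be non-negative and non-missing")
  s <- sum(raw)
  if (s <= 0) stop2("at least one weight must be positive")
  raw / s
}

#' Population-weighted spatial average of station temperatures
#'
#' Collapses multi-station daily records into a single representative daily
#' series by weighting each station's value with its (normalized) population
#' weight. On days where some stations do not report, the weights are
#' renormalized over the reporting stations; days with no reporting station
#' are missing (`NA`).
#'
#' @param stations data frame with columns `station_id`, `date` and at least
#'   one of `t_mean`, `t_max`, `t_min`.
#' @param weights named weights as accepted by [normalize_weights()].
#' @param metric which daily metric to aggregate: `"mean"`, `"max"` or
#'   `"min"`.
#' @return data frame of class `"exposure_series"` with columns `date` and
#'   `temp`, one row per calendar day of the full observed range (gaps
#'   explicit as `NA`), and attribute `metric`.
#' @export
weighted_exposure <- function(stations, weights, metric = c("mean", "max", "min")) {
  metric <- match.arg(metric)
  col <- paste0("t_", metric)
  if (!col %in% names(stations)) stop2("metric column '%s' absent from station records", col)
  w <- normalize_weights(weights)
  stations <- stations[as.character(stations$station_id) %in% names(w), ]
  if (!nrow(stations)) stop2("no station in the records matches the weight table")
  if (anyDuplicated(stations[c("station_id", "date")]))
    stop2("duplicate (station, date) rows in station records")
  dates <- as.Date(stations$date)
  val <- as.numeric(stations[[col]])
  keep <- !is.na(val)
  dates <- dates[keep]; val <- val[keep]
  wd <- w[as.character(stations$station_id)[keep]]
  full <- seq(min(dates), max(dates), by = "day")
  idx <- match(dates, full)
  num <- rowsum(val * wd, idx)
  den <- rowsum(wd, idx)
  temp <- rep(NA_real_, length(full))
  temp[as.integer(rownames(num))] <- num[, 1] / den[, 1]
  structure(data.frame(date = full, temp = temp),
            metric = metric, class = c("exposure_series", "data.frame"))
}

#' Reference and tail summaries of a temperature series
#'
#' Computes the reference temperature (the series median, against which all
#' relative risks are expressed), the empirical 90th/95th/99th percentiles
#' and the maximum, together with the integer evaluation grid used for
#' lag-slice plots: percentiles are rounded up (they stay inside the recorded
#' range) while the maximum is rounded down so the integer cannot fall
#' outside it.
#'
#' Percentiles use linear interpolation between order statistics
#' (`quantile(type = 7)`); the median of an even-length series is the mean of
#' the two central order statistics.
#'
#' @param series an exposure series from [weighted_exposure()] or a numeric
#'   vector of daily temperatures.
#' @return list of class `"temperature_summary"` with elements `reference`,
#'   `p90`, `p95`, `p99`, `upper_limit` and integer `grid` (named `p90`,
#'   `p95`, `p99`, `max`).
#' @export
temperature_summary <- function(series) {
  x <- if (is.data.frame(series)) series$temp else as.numeric(series)
  x <- x[!is.na(x)]
  if (length(x) < 2) stop2("need at least two non-missing temperatures")
  q <- stats::quantile(x, c(0.5, 0.90, 0.95, 0.99), type = 7, names = FALSE)
  out <- list(reference = q[1], p90 = q[2], p95 = q[3], p99 = q[4],
              upper_limit = max(x),
              grid = c(p90 = ceiling(q[2]), p95 = ceiling(q[3]),
                       p99 = ceiling(q[4]), max = floor(max(x))))
  class(out) <- "temperature_summary"
  out
}

#' @export
print.temperature_summary <- function(x, ...) {
  cat("Temperature summary (degC)\n")
  cat(sprintf("  reference (median): %.1f\n", x$reference))
  cat(sprintf("  p90 %.1f  p95 %.1f  p99 %.1f  max %.1f\n",
              x$p90, x$p95, x$p99, x$upper_limit))
  cat(sprintf("  integer grid: p90 %d, p95 %d, p99 %d, max %d\n",
              x$grid["p90"], x$grid["p95"], x$grid["p99"], x$grid["max"]))
  invisible(x)
}
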