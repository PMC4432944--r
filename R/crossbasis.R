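#' Cross-basis specification
#'
#' Describes the two marginal bases of a distributed lag non-linear model
#' (DLNM): a quadratic B-spline over temperature and a natural cubic spline
#' over lag, whose tensor product forms the cross-basis. Defaults follow the
#' common choices for daily temperature-mortality analyses: maximum lag 10
#' days and 4 degrees of freedom in each dimension.
#'
#' Interior knots of the temperature spline default to evenly distributed
#' percentiles of the observed series (for `var_df = 4`, `var_degree = 2`
#' that is two knots at the 33.33rd and 66.67th percentiles); boundary knots
#' sit at the observed range. Both are resolved when the spec first meets
#' data (see [crossbasis()]) and are frozen thereafter so that predictions
#' reuse the fitting-time basis.
#'
#' The lag spline includes its intercept column, so a constant-in-lag (and in
#' particular a lag-0) effect is representable; with the intercept, `lag_df`
#' columns correspond to `lag_df - 2` interior knots between the boundary
#' knots at lag 0 and lag `max_lag`. Interior lag knots are placed at equally
#' spaced quantiles of the integer lags (`lag_knot_spacing = "linear"`, the
#' default) or equally spaced on the log scale between lag 1 and `max_lag`
#' (`"log"`).
#'
#' @param max_lag maximum lag in days (default 10).
#' @param var_df degrees of freedom of the temperature basis (default 4).
#' @param var_degree polynomial degree of the temperature B-spline (default
#'   2, quadratic).
#' @param var_knots interior knot positions in degrees C, or `NULL` to place
#'   them at evenly distributed percentiles of the data.
#' @param var_boundary length-2 boundary knots in degrees C, or `NULL` for
#'   the observed range.
#' @param lag_df degrees of freedom of the lag basis (default 4).
#' @param lag_knot_spacing `"linear"` or `"log"` interior-knot placement on
#'   the lag axis.
#' @return An object of class `"cb_spec"`.
#' @seealso [crossbasis()], [temperature_basis()], [lag_basis()]
#' @export
cb_spec <- function(max_lag = 10L, var_df = 4L, var_degree = 2L,
                    var_knots = NULL, var_boundary = NULL,
                    lag_df = 4L, lag_knot_spacing = c("linear", "log")) {
  lag_knot_spacing <- match.arg(lag_knot_spacing)
  if (!is_count(max_lag) || max_lag < 1) stop2("max_lag must be an integer >= 1")
  if (!is_count(var_df) || !is_count(var_degree) || !is_count(lag_df))
    stop2("var_df, var_degree and lag_df must be integers")
  if (var_df < var_degree + 1)
    stop2("var_df must be at least var_degree + 1 (got %d < %d)",
          var_df, var_degree + 1)
  if (lag_df < 2) stop2("lag_df must be >= 2")
  if (lag_df - 2 > max_lag - 1)
    stop2("lag_df = %d needs %d interior lag knots but only %d integer lags lie strictly between 0 and %d",
          lag_df, lag_df - 2, max_lag - 1, max_lag)
  if (!is.null(var_boundary) && (length(var_boundary) != 2 ||
      diff(var_boundary) <= 0))
    stop2("var_boundary must be two increasing values")
  structure(list(max_lag = as.integer(max_lag), var_df = as.integer(var_df),
                 var_degree = as.integer(var_degree),
                 var_knots = var_knots, var_boundary = var_boundary,
                 lag_df = as.integer(lag_df),
                 lag_knot_spacing = lag_knot_spacing),
            class = "cb_spec")
}

#' @export
print.cb_spec <- function(x, ...) {
  cat("Cross-basis specification\n")
  cat(sprintf("  temperature: B-spline, degree %d, df %d", x$var_degree, x$var_df))
  if (!is.null(x$var_knots))
    cat(sprintf(", knots at %s degC, boundary [%s]",
                paste(signif(x$var_knots, 4), collapse = ", "),
                paste(signif(x$var_boundary, 4), collapse = ", ")))
  cat("\n")
  cat(sprintf("  lag:         natural cubic spline, df %d over lags 0..%d (%s knot spacing)\n",
              x$lag_df, x$max_lag, x$lag_knot_spacing))
  cat(sprintf("  cross-basis parameters: %d\n", x$var_df * x$lag_df))
  invisible(x)
}

# Fill data-dependent fields (temperature knots/boundary) from an observed
# series. Idempotent once resolved.
resolve_spec <- function(spec, x) {
  stopifnot(inherits(spec, "cb_spec"))
  x <- x[is.finite(x)]
  if (is.null(spec$var_boundary)) spec$var_boundary <- range(x)
  if (is.null(spec$var_knots)) {
    m <- spec$var_df - spec$var_degree      # interior knot count
    probs <- seq_len(m) / (m + 1)           # evenly distributed percentiles
    spec$var_knots <- unname(stats::quantile(x, probs, type = 7))
  }
  if (any(spec$var_knots <= spec$var_boundary[1]) ||
      any(spec$var_knots >= spec$var_boundary[2]))
    stop2("temperature knots must lie strictly inside the boundary")
  spec
}

interior_lag_knots <- function(spec) {
  m <- spec$lag_df - 2L
  if (m == 0L) return(numeric(0))
  if (spec$lag_knot_spacing == "linear") {
    unname(stats::quantile(0:spec$max_lag, seq_len(m) / (m + 1), type = 7))
  } else {
    exp(seq(log(1), log(spec$max_lag), length.out = m + 2))[seq_len(m) + 1]
  }
}

#' Temperature basis of a cross-basis specification
#'
#' Evaluates the quadratic (or other degree) B-spline basis of `spec` at the
#' supplied temperatures. The basis has no intercept column; values beyond
#' the boundary knots are evaluated by polynomial extension of the boundary
#' pieces rather than clipped.
#'
#' @param x numeric vector of temperatures in degrees C.
#' @param spec a [cb_spec()] whose temperature knots have been resolved
#'   against data (as done by [crossbasis()]), or one with explicit
#'   `var_knots`/`var_boundary`.
#' @return numeric matrix with `length(x)` rows and `spec$var_df` columns;
#'   rows for `NA` temperatures are `NA`.
#' @export
temperature_basis <- function(x, spec) {
  if (is.null(spec$var_knots) || is.null(spec$var_boundary))
    stop2("spec has unresolved temperature knots; build a crossbasis first or set var_knots/var_boundary")
  if (any(is.infinite(x))) stop2("non-finite temperatures in x")
  out <- matrix(NA_real_, length(x), spec$var_df)
  ok <- !is.na(x)
  if (any(ok)) {
    b <- suppressWarnings(splines::bs(
      x[ok], knots = spec$var_knots, degree = spec$var_degree,
      Boundary.knots = spec$var_boundary, intercept = FALSE))
    out[ok, ] <- b[, seq_len(spec$var_df), drop = FALSE]
  }
  colnames(out) <- paste0("v", seq_len(spec$var_df))
  out
}

#' Lag basis of a cross-basis specification
#'
#' Natural cubic spline basis (intercept included) evaluated at the integer
#' lags `0..max_lag`, with boundary knots at 0 and `max_lag` so the spline is
#' linear beyond them and has zero second derivative at both ends.
#'
#' @param spec a [cb_spec()].
#' @return numeric matrix of dimension `(max_lag + 1) x lag_df`.
#' @export
lag_basis <- function(spec) {
  kn <- interior_lag_knots(spec)
  C <- splines::ns(0:spec$max_lag, knots = if (length(kn)) kn,
                   Boundary.knots = c(0, spec$max_lag), intercept = TRUE)
  C <- matrix(C, nrow = spec$max_lag + 1L,
              dimnames = list(NULL, paste0("l", seq_len(spec$lag_df))))
  C
}

#' Build the DLNM cross-basis of a daily exposure series
#'
#' For each day `t` the cross-basis row holds, for every pair of one
#' temperature-basis function `B_i` and one lag-basis function `C_j`, the sum
#' over lags `l = 0..max_lag` of `B_i(x[t-l]) * C_j(l)`. Fitting a Poisson
#' regression on these columns estimates a full exposure-lag-response
#' surface.
#'
#' The first `max_lag` rows (and any row whose lag window contains a missing
#' temperature) have incomplete exposure history; they are filled with `NA`
#' and flagged invalid so that model fitting excludes them rather than
#' fabricating pre-study exposure.
#'
#' @param x numeric vector of daily temperatures (degrees C), one value per
#'   consecutive calendar day, or an exposure series as returned by
#'   [weighted_exposure()].
#' @param dates optional `Date` vector aligned with `x` (taken from the
#'   exposure series when `x` is one).
#' @param spec a [cb_spec()]; data-dependent knots are resolved against `x`.
#' @return A numeric matrix of class `"crossbasis"` with
#'   `var_df * lag_df` columns and attributes `spec` (the resolved
#'   [cb_spec()]), `valid` (logical row mask) and `dates`.
#' @examples
#' x <- 20 + 8 * sin(2 * pi * seq_len(400) / 365) + rnorm(400)
#' cb <- crossbasis(x, spec = cb_spec(max_lag = 10, var_df = 4, lag_df = 4))
#' dim(cb)           # 400 x 16
#' sum(!attr(cb, "valid"))  # the 10 warm-up days
#' @export
crossbasis <- function(x, dates = NULL, spec = cb_spec()) {
  if (is.data.frame(x)) {
    if (is.null(dates) && "date" %in% names(x)) dates <- x$date
    x <- x$temp
  }
  x <- as.numeric(x)
  L <- spec$max_lag
  n <- length(x)
  if (n < L + 1) stop2("exposure series must cover at least max_lag + 1 = %d days", L + 1)
  if (!is.null(dates)) {
    dates <- assert_daily_dates(dates, "exposure dates")
    if (length(dates) != n) stop2("dates and x lengths differ")
  }
  spec <- resolve_spec(spec, x)
  B <- temperature_basis(x, spec)           # n x var_df
  C <- lag_basis(spec)                      # (L+1) x lag_df
  vdf <- spec$var_df; ldf <- spec$lag_df
  cb <- matrix(0, n, vdf * ldf)
  for (l in 0:L) {
    Q <- matrix(NA_real_, n, vdf)
    Q[(l + 1):n, ] <- B[seq_len(n - l), , drop = FALSE]
    cb <- cb + Q[, rep(seq_len(vdf), each = ldf), drop = FALSE] *
      matrix(C[l + 1, ], n, vdf * ldf, byrow = TRUE)
  }
  colnames(cb) <- paste0("v", rep(seq_len(vdf), each = ldf),
                         ".l", rep(seq_len(ldf), vdf))
  valid <- stats::complete.cases(cb)
  valid[seq_len(L)] <- FALSE
  cb[!valid, ] <- NA_real_
  structure(cb, spec = spec, valid = valid, dates = dates,
            class = c("crossbasis", class(cb)))
}

#' @export
print.crossbasis <- function(x, ...) {
  s <- attr(x, "spec")
  cat(sprintf("DLNM cross-basis: %d days x %d columns (%d valid rows)\n",
              nrow(x), ncol(x), sum(attr(x, "valid"))))
  print(s)
  invisible(x)
}

#' Write / read a cross-basis as a self-describing text matrix
#'
#' The header lines (prefixed `#`) encode the resolved specification so a fit
#' can be reproduced from the saved artifact alone.
#'
#' @param cb a [crossbasis()] matrix.
#' @param path file path.
#' @return `read_crossbasis()` returns the reconstructed `"crossbasis"`
#'   matrix; `write_crossbasis()` returns `path` invisibly.
#' @export
write_crossbasis <- function(cb, path) {
  s <- attr(cb, "spec")
  hdr <- c(
    sprintf("# max_lag=%d var_df=%d var_degree=%d lag_df=%d lag_knot_spacing=%s",
            s$max_lag, s$var_df, s$var_degree, s$lag_df, s$lag_knot_spacing),
    sprintf("# var_knots=%s", paste(format(s$var_knots, digits = 17), collapse = ",")),
    sprintf("# var_boundary=%s", paste(format(s$var_boundary, digits = 17), collapse = ",")))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  dat <- data.frame(date = if (is.null(attr(cb, "dates"))) seq_len(nrow(cb))
                    else attr(cb, "dates"),
                    valid = attr(cb, "valid"))
  dat <- cbind(dat, as.data.frame(unclass(cb)))
  utils::write.table(dat, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_crossbasis
#' @export
read_crossbasis <- function(path) {
  hdr <- readLines(path, n = 3)
  kv <- function(line) {
    parts <- strsplit(sub("^# ", "", line), " ")[[1]]
    out <- strsplit(parts, "=")
    stats::setNames(vapply(out, `[`, "", 2), vapply(out, `[`, "", 1))
  }
  h1 <- kv(hdr[1])
  num <- function(line) as.numeric(strsplit(sub("^# [a-z_]+=", "", line), ",")[[1]])
  spec <- cb_spec(max_lag = as.integer(h1["max_lag"]),
                  var_df = as.integer(h1["var_df"]),
                  var_degree = as.integer(h1["var_degree"]),
                  var_knots = num(hdr[2]), var_boundary = num(hdr[3]),
                  lag_df = as.integer(h1["lag_df"]),
                  lag_knot_spacing = h1[["lag_knot_spacing"]])
  dat <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  m <- as.matrix(dat[, -(1:2), drop = FALSE])
  dates <- tryCatch(as.Date(dat$date), error = function(e) NULL)
  if (!is.null(dates) && anyNA(dates)) dates <- NULL
  structure(m, spec = spec, valid = dat$valid, dates = dates,
            class = c("crossbasis", class(m)))
}
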