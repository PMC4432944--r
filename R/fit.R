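#' Time-stratified case-crossover strata
#'
#' Assigns every analysis date to a stratum. Within a stratum each death day
#' is compared only to other days of the same stratum, so confounders that
#' vary slowly (season, long-term trends) are removed by design. The default
#' scheme is one stratum per calendar year-month; fixed-length windows of 30,
#' 28 or 21 days (anchored at the first date, final window possibly shorter)
#' are available for sensitivity analysis.
#'
#' @param dates contiguous daily `Date` vector.
#' @param scheme `"calendar_month"` or `"fixed_window"`.
#' @param window window length in days (required for `"fixed_window"`;
#'   values below 7 are rejected as degenerate).
#' @return factor of stratum labels aligned with `dates`, with attribute
#'   `scheme`.
#' @examples
#' d <- seq(as.Date("2004-01-01"), as.Date("2004-03-31"), by = "day")
#' table(make_strata(d))
#' table(make_strata(d, "fixed_window", window = 28))
#' @export
make_strata <- function(dates, scheme = c("calendar_month", "fixed_window"),
                        window = NULL) {
  scheme <- match.arg(scheme)
  dates <- assert_daily_dates(dates)
  if (scheme == "calendar_month") {
    lab <- format(dates, "%Y-%m")
  } else {
    if (is.null(window) || !is_count(window))
      stop2("fixed_window scheme needs an integer 'window'")
    if (window < 7) stop2("window length %d is degenerate (< 7 days)", window)
    lab <- sprintf("w%03d", (seq_along(dates) - 1L) %/% as.integer(window) + 1L)
  }
  structure(factor(lab, levels = unique(lab)),
            scheme = if (scheme == "calendar_month") scheme
                     else sprintf("fixed_window:%d", window))
}

# Shared GLM worker for the case-crossover and time-series designs.
# `season` is a matrix of seasonal columns (stratum indicators already
# expanded, or a time spline); returns the fitted "cc_fit" object.
fit_dlnm_glm <- function(y, cb, dates, season, dow, design, extra_meta = list()) {
  valid <- if (is.null(cb)) rep(TRUE, length(y)) else attr(cb, "valid")
  if (!is.null(cb) && length(y) != nrow(cb))
    stop2("counts and cross-basis have different lengths")
  keep <- valid & !is.na(y)
  X <- cbind("(Intercept)" = 1,
             if (!is.null(cb)) cb[keep, , drop = FALSE],
             season[keep, , drop = FALSE])
  if (dow) {
    dw <- stats::model.matrix(~dowf, data.frame(dowf = dow_factor(dates[keep])))
    X <- cbind(X, dw[, -1, drop = FALSE])
  }
  yk <- y[keep]
  fit <- stats::glm.fit(X, yk, family = stats::quasipoisson(),
                        control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged)
    stop2("%s fit did not converge in 100 IRLS iterations (deviance %.6g)",
          design, fit$deviance)
  co <- fit$coefficients
  if (anyNA(co))
    stop2("design matrix is rank deficient; collinear columns: %s",
          paste(names(co)[is.na(co)], collapse = ", "))
  n <- length(yk); k <- length(co)
  mu <- fit$fitted.values
  pearson <- sum((yk - mu)^2 / mu)
  dispersion <- pearson / (n - k)
  # covariance = dispersion * (X'WX)^-1 from the final IRLS weighted QR,
  # un-pivoted back to coefficient order
  p <- fit$rank
  piv <- fit$qr$pivot[seq_len(p)]
  cov_piv <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  cov_unscaled <- matrix(0, p, p, dimnames = list(names(co), names(co)))
  cov_unscaled[piv, piv] <- cov_piv
  # Poisson log-likelihood at the optimum; written out so that non-integer
  # working responses (e.g. expected counts) are handled silently
  loglik <- sum(yk * log(mu) - mu - lgamma(yk + 1))
  ic <- quasi_ic(loglik, dispersion, k, n)
  cb_names <- if (is.null(cb)) character(0) else colnames(cb)
  structure(c(list(
    coefficients = co,
    vcov = dispersion * cov_unscaled,
    dispersion = dispersion,
    loglik = loglik, k = k, n = n,
    qaic = ic[["QAIC"]], qbic = ic[["QBIC"]],
    deviance = fit$deviance, iter = fit$iter, converged = fit$converged,
    spec = attr(cb, "spec"),
    cb_names = cb_names,
    fitted = mu, y = yk, dates = dates[keep],
    design = design), extra_meta), class = "cc_fit")
}

#' Fit the case-crossover DLNM by overdispersed Poisson regression
#'
#' Fits `log(mu_t) = alpha + beta * CB_t + lambda * Strata_t + eta * DOW_t`
#' by iteratively reweighted least squares, where `CB_t` is the cross-basis
#' row of day `t`, `Strata_t` the case-crossover stratum indicators and
#' `DOW_t` day-of-week indicators. Overdispersion `phi` is estimated as the
#' Pearson statistic divided by the residual degrees of freedom, and the
#' coefficient covariance is `phi` times the inverse Fisher information
#' (quasi-likelihood). QAIC and QBIC are attached for model selection.
#'
#' Days with incomplete lag history (the first `max_lag` days and any day
#' whose window spans a temperature gap) are excluded from the likelihood.
#' Strata with zero total count carry no information about `beta` beyond
#' their own indicator; they are dropped with a warning.
#'
#' @param counts daily aggregate death counts: numeric vector aligned with
#'   the cross-basis rows, or a data frame with `date` and `count`.
#' @param cb a [crossbasis()] matrix, or `NULL` for a baseline model without
#'   temperature terms.
#' @param dates daily `Date` vector (defaults to the cross-basis dates).
#' @param strata stratum factor from [make_strata()] (default: calendar
#'   year-month strata).
#' @param dow include day-of-week indicator terms (reference Monday).
#' @return object of class `"cc_fit"` with components `coefficients`,
#'   `vcov`, `dispersion`, `loglik`, `k`, `n`, `qaic`, `qbic`, `spec` and
#'   standard methods (`print`, `summary`, `coef`, `vcov`, `logLik`,
#'   `residuals`, `predict`).
#' @seealso [predict.cc_fit()], [information_criteria()], [select_df()]
#' @export
cc_fit <- function(counts, cb, dates = attr(cb, "dates"), strata = NULL,
                   dow = TRUE) {
  if (is.data.frame(counts)) {
    if (is.null(dates)) dates <- as.Date(counts$date)
    counts <- counts$count
  }
  if (is.null(dates)) stop2("dates are needed (none attached to the cross-basis)")
  dates <- assert_daily_dates(dates)
  if (is.null(strata)) strata <- make_strata(dates)
  if (length(strata) != length(counts)) stop2("strata and counts lengths differ")
  keep0 <- (if (is.null(cb)) rep(TRUE, length(counts)) else attr(cb, "valid")) &
    !is.na(counts)
  tot <- tapply(counts[keep0], strata[keep0], sum)
  empty <- names(tot)[!is.na(tot) & tot == 0]
  if (length(empty)) {
    warn2("dropping %d strata with zero total count: %s",
          length(empty), paste(empty, collapse = ", "))
    drop <- strata %in% empty
    counts[drop] <- NA  # excluded via the NA mask
  }
  sf <- factor(strata, levels = setdiff(levels(strata), empty))
  # rows of dropped strata are already excluded via the NA count mask; park
  # them on the reference level so the indicator matrix keeps full length
  sf[is.na(sf)] <- levels(sf)[1]
  S <- if (nlevels(sf) > 1)
    stats::model.matrix(~sf, data.frame(sf = sf))[, -1, drop = FALSE]
  else matrix(0, length(sf), 0)
  fit_dlnm_glm(counts, cb, dates, S, dow, design = "case-crossover",
               extra_meta = list(strata_scheme = attr(strata, "scheme"),
                                 n_strata = nlevels(sf)))
}

#' Fit the time-series alternative design
#'
#' Replaces the case-crossover stratum indicators with a natural cubic
#' spline over calendar time (default 7 df per year) to model seasonal and
#' long-term trends, keeping the cross-basis and day-of-week terms. Used as
#' a cross-design check on the case-crossover estimates.
#'
#' @inheritParams cc_fit
#' @param seasonal_df_per_year spline df per year of data (default 7).
#' @return a `"cc_fit"` object with `design = "timeseries"`.
#' @export
ts_fit <- function(counts, cb, dates = attr(cb, "dates"), dow = TRUE,
                   seasonal_df_per_year = 7) {
  if (is.data.frame(counts)) {
    if (is.null(dates)) dates <- as.Date(counts$date)
    counts <- counts$count
  }
  dates <- assert_daily_dates(dates)
  df <- max(1L, round(seasonal_df_per_year * length(dates) / 365.25))
  S <- splines::ns(as.numeric(dates), df = df)
  colnames(S) <- paste0("time", seq_len(ncol(S)))
  fit_dlnm_glm(counts, cb, dates, S, dow, design = "timeseries",
               extra_meta = list(seasonal_df = df))
}

#' Quasi-likelihood information criteria
#'
#' `QAIC = -2 L + 2 phi k` and `QBIC = -2 L + log(n) phi k`, where `L` is
#' the Poisson log-likelihood at the fitted parameters, `phi` the estimated
#' overdispersion, `k` the number of parameters and `n` the number of
#' observations. With `phi = 1` QAIC reduces to the ordinary AIC.
#'
#' @param loglik Poisson log-likelihood at the optimum.
#' @param dispersion estimated overdispersion `phi`.
#' @param k total parameter count.
#' @param n number of observations.
#' @return named numeric vector `c(QAIC =, QBIC =)`.
#' @export
quasi_ic <- function(loglik, dispersion, k, n)
  c(QAIC = -2 * loglik + 2 * dispersion * k,
    QBIC = -2 * loglik + log(n) * dispersion * k)

#' @rdname quasi_ic
#' @param fit a converged `"cc_fit"`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "cc_fit"))
  quasi_ic(fit$loglik, fit$dispersion, fit$k, fit$n)
}

#' Select spline degrees of freedom by QAIC/QBIC
#'
#' Fits the case-crossover model for every combination of temperature and
#' lag degrees of freedom on a grid (default `{4,5,6} x {4,5,6}`) and
#' returns the specification minimizing QAIC, together with both criteria
#' for every candidate. When QAIC and QBIC point at different combinations,
#' QAIC wins and the disagreement is reported via `message()`.
#'
#' @inheritParams cc_fit
#' @param exposure exposure series ([weighted_exposure()] output or numeric
#'   vector) used to rebuild the cross-basis at each candidate df.
#' @param var_df,lag_df integer grids of candidate degrees of freedom.
#' @param max_lag maximum lag of all candidate bases.
#' @param lag_knot_spacing passed to [cb_spec()].
#' @return list of class `"df_selection"`: `spec` (winning [cb_spec()]),
#'   `table` (one row per candidate: df pair, QAIC, QBIC, dispersion).
#' @export
select_df <- function(counts, exposure, dates = NULL, var_df = 4:6,
                      lag_df = 4:6, max_lag = 10L, strata = NULL, dow = TRUE,
                      lag_knot_spacing = "linear") {
  if (!length(var_df) || !length(lag_df)) stop2("df grids must be non-empty")
  grid <- expand.grid(var_df = var_df, lag_df = lag_df)
  rows <- vector("list", nrow(grid))
  specs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      spec <- cb_spec(max_lag = max_lag, var_df = grid$var_df[i],
                      lag_df = grid$lag_df[i],
                      lag_knot_spacing = lag_knot_spacing)
      cbm <- crossbasis(exposure, dates = dates, spec = spec)
      fit <- cc_fit(counts, cbm, strata = strata, dow = dow)
      specs[[i]] <- attr(cbm, "spec")
      data.frame(var_df = grid$var_df[i], lag_df = grid$lag_df[i],
                 qaic = fit$qaic, qbic = fit$qbic,
                 dispersion = fit$dispersion)
    }, error = function(e) {
      warn2("df candidate (%d, %d) failed: %s", grid$var_df[i],
            grid$lag_df[i], conditionMessage(e))
      NULL
    })
    rows[[i]] <- res
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab)) stop2("every df candidate failed")
  best_aic <- which.min(tab$qaic)
  best_bic <- which.min(tab$qbic)
  if (best_aic != best_bic)
    message(sprintf(
      "QAIC selects (%d, %d) but QBIC selects (%d, %d); keeping the QAIC choice",
      tab$var_df[best_aic], tab$lag_df[best_aic],
      tab$var_df[best_bic], tab$lag_df[best_bic]))
  idx <- which(grid$var_df == tab$var_df[best_aic] &
               grid$lag_df == tab$lag_df[best_aic])
  structure(list(spec = specs[[idx]], table = tab,
                 qaic_choice = c(tab$var_df[best_aic], tab$lag_df[best_aic]),
                 qbic_choice = c(tab$var_df[best_bic], tab$lag_df[best_bic])),
            class = "df_selection")
}

#' @export
print.df_selection <- function(x, ...) {
  cat("Degrees-of-freedom selection (QAIC-minimizing candidate kept)\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("selected: var_df = %d, lag_df = %d\n",
              x$qaic_choice[1], x$qaic_choice[2]))
  invisible(x)
}

#' @export
print.cc_fit <- function(x, ...) {
  cat(sprintf("DLNM %s fit (quasi-Poisson)\n", x$design))
  cat(sprintf("  n = %d days, k = %d parameters, %d cross-basis terms\n",
              x$n, x$k, length(x$cb_names)))
  cat(sprintf("  dispersion phi = %.3f, logLik = %.2f\n", x$dispersion, x$loglik))
  cat(sprintf("  QAIC = %.1f, QBIC = %.1f\n", x$qaic, x$qbic))
  invisible(x)
}

#' @export
summary.cc_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(fit = object, coef_table = tab)
  class(out) <- "summary.cc_fit"
  out
}

#' @export
print.summary.cc_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCross-basis coefficients:\n")
  stats::printCoefmat(x$coef_table[x$fit$cb_names, , drop = FALSE])
  invisible(x)
}

#' @export
coef.cc_fit <- function(object, ...) object$coefficients

#' @export
vcov.cc_fit <- function(object, ...) object$vcov

#' @export
logLik.cc_fit <- function(object, ...)
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")

#' @export
residuals.cc_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "pearson") r <- r / sqrt(object$fitted)
  r
}

#' @export
fitted.cc_fit <- function(object, ...) object$fitted

# beta block (cross-basis coefficients) and its covariance
cb_coef <- function(fit) fit$coefficients[fit$cb_names]
cb_vcov <- function(fit) fit$vcov[fit$cb_names, fit$cb_names, drop = FALSE]
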