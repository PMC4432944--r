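#' Relative-risk surface of a fitted DLNM
#'
#' Transforms the cross-basis coefficients of a fit into relative risks on a
#' temperature-by-lag grid, expressed against a reference temperature
#' (conventionally the series median). For temperature `x` and lag `l` the
#' log relative risk is the contrast
#' `sum_ij (B_i(x) - B_i(ref)) * C_j(l) * beta_ij`, its variance follows
#' from the same contrast vector and the coefficient covariance, and 95%
#' Wald bounds are exponentiated. At the reference temperature the contrast
#' vanishes, so `RR = 1` with a degenerate interval at every lag, exactly.
#'
#' @param fit a `"cc_fit"` object.
#' @param temperatures numeric vector of temperatures (degC) at which to
#'   evaluate the surface.
#' @param reference reference temperature; must lie inside the basis
#'   boundary knots.
#' @param level confidence level (default 0.95).
#' @return data frame of class `"rr_surface"` with columns `temperature`,
#'   `lag`, `logrr`, `se`, `rr`, `lo`, `hi`, and attributes `reference`,
#'   `level`, `spec`, `design`.
#' @seealso [cumulative_rr()], [lag_slice()], [temperature_slice()],
#'   [rr_grid()]
#' @export
predict_rr <- function(fit, temperatures, reference, level = 0.95) {
  stopifnot(inherits(fit, "cc_fit"))
  spec <- fit$spec
  if (length(reference) != 1 || is.na(reference))
    stop2("reference must be a single temperature")
  if (reference < spec$var_boundary[1] || reference > spec$var_boundary[2])
    stop2("reference %.2f lies outside the basis boundary [%.2f, %.2f]",
          reference, spec$var_boundary[1], spec$var_boundary[2])
  beta <- cb_coef(fit)
  V <- cb_vcov(fit)
  if (length(beta) != spec$var_df * spec$lag_df)
    stop2("fit and specification disagree on cross-basis dimension")
  Bdiff <- temperature_basis(temperatures, spec) -
    matrix(temperature_basis(reference, spec), length(temperatures),
           spec$var_df, byrow = TRUE)
  C <- lag_basis(spec)
  L <- spec$max_lag
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- vector("list", L + 1L)
  for (l in 0:L) {
    # contrast rows: kronecker ordering matches column order v{i}.l{j}
    W <- Bdiff[, rep(seq_len(spec$var_df), each = spec$lag_df), drop = FALSE] *
      matrix(C[l + 1, ], nrow(Bdiff), spec$var_df * spec$lag_df, byrow = TRUE)
    logrr <- drop(W %*% beta)
    se <- sqrt(pmax(0, rowSums((W %*% V) * W)))
    out[[l + 1L]] <- data.frame(temperature = temperatures, lag = l,
                                logrr = logrr, se = se)
  }
  res <- do.call(rbind, out)
  res$rr <- exp(res$logrr)
  res$lo <- exp(res$logrr - z * res$se)
  res$hi <- exp(res$logrr + z * res$se)
  structure(res, reference = reference, level = level, spec = spec,
            design = fit$design, class = c("rr_surface", "data.frame"))
}

#' Overall (lag-cumulated) relative risk
#'
#' Sums the log relative risk over all lags `0..max_lag` at each
#' temperature — the net risk of one day at temperature `x` accumulated over
#' the following `max_lag` days — with the variance from the summed contrast
#' vector.
#'
#' @inheritParams predict_rr
#' @return data frame of class `"cum_rr"` with columns `temperature`,
#'   `logrr`, `se`, `rr`, `lo`, `hi`.
#' @export
cumulative_rr <- function(fit, temperatures, reference, level = 0.95) {
  stopifnot(inherits(fit, "cc_fit"))
  spec <- fit$spec
  if (reference < spec$var_boundary[1] || reference > spec$var_boundary[2])
    stop2("reference %.2f lies outside the basis boundary", reference)
  beta <- cb_coef(fit)
  V <- cb_vcov(fit)
  Bdiff <- temperature_basis(temperatures, spec) -
    matrix(temperature_basis(reference, spec), length(temperatures),
           spec$var_df, byrow = TRUE)
  csum <- colSums(lag_basis(spec))
  W <- Bdiff[, rep(seq_len(spec$var_df), each = spec$lag_df), drop = FALSE] *
    matrix(csum, nrow(Bdiff), spec$var_df * spec$lag_df, byrow = TRUE)
  logrr <- drop(W %*% beta)
  se <- sqrt(pmax(0, rowSums((W %*% V) * W)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(data.frame(temperature = temperatures, logrr = logrr, se = se,
                       rr = exp(logrr), lo = exp(logrr - z * se),
                       hi = exp(logrr + z * se)),
            reference = reference, level = level,
            class = c("cum_rr", "data.frame"))
}

#' Default temperature grid for surface prediction
#'
#' 0.1-degC steps over the observed range, augmented with the integer
#' evaluation points of a [temperature_summary()] (rounded percentiles and
#' rounded-down maximum) when supplied.
#'
#' @param fit a `"cc_fit"` (its basis boundary defines the range) or a
#'   length-2 numeric range.
#' @param summary optional [temperature_summary()].
#' @return sorted numeric vector of temperatures.
#' @export
rr_grid <- function(fit, summary = NULL) {
  rng <- if (inherits(fit, "cc_fit")) fit$spec$var_boundary else range(fit)
  g <- seq(ceiling(rng[1] * 10) / 10, floor(rng[2] * 10) / 10, by = 0.1)
  if (!is.null(summary)) g <- c(g, as.numeric(summary$grid))
  sort(unique(round(g, 6)))
}

#' @describeIn predict_rr `predict` method: `cumulative = TRUE` delegates to
#'   [cumulative_rr()], otherwise to [predict_rr()].
#' @param object a `"cc_fit"`.
#' @param cumulative return the lag-cumulated risk instead of the surface.
#' @param ... unused.
#' @export
predict.cc_fit <- function(object, temperatures, reference,
                           cumulative = FALSE, level = 0.95, ...) {
  if (missing(temperatures)) temperatures <- rr_grid(object)
  if (cumulative) cumulative_rr(object, temperatures, reference, level)
  else predict_rr(object, temperatures, reference, level)
}

match_grid <- function(have, want, what) {
  idx <- vapply(want, function(v) {
    j <- which(abs(have - v) < 1e-8)
    if (!length(j)) stop2("%s %.4g is not on the surface grid; rebuild the surface including it", what, v)
    j[1]
  }, integer(1))
  idx
}

#' Lag-specific slices of a relative-risk surface
#'
#' Extracts `RR(l)` for `l = 0..max_lag` at the requested temperatures
#' (typically the integer grid values of the 90th/95th/99th percentiles and
#' the maximum). Values are the surface cells themselves; no interpolation.
#'
#' @param surface an `"rr_surface"` from [predict_rr()].
#' @param at_temperatures temperatures that must be present on the surface
#'   grid.
#' @return data frame `temperature`, `lag`, `rr`, `lo`, `hi`.
#' @export
lag_slice <- function(surface, at_temperatures) {
  stopifnot(inherits(surface, "rr_surface"))
  tg <- sort(unique(surface$temperature))
  tt <- tg[match_grid(tg, at_temperatures, "temperature")]
  out <- as.data.frame(surface)[surface$temperature %in% tt,
                                c("temperature", "lag", "rr", "lo", "hi")]
  out <- out[order(out$temperature, out$lag), ]
  rownames(out) <- NULL
  out
}

#' Temperature-response slices at fixed lags
#'
#' Extracts `RR(x)` along the temperature grid at the requested lags
#' (e.g. lags 0, 1, 2 and 4). Each slice passes through `RR = 1` at the
#' reference temperature.
#'
#' @param surface an `"rr_surface"`.
#' @param at_lags integer lags present on the surface.
#' @return data frame `temperature`, `lag`, `rr`, `lo`, `hi`.
#' @export
temperature_slice <- function(surface, at_lags) {
  stopifnot(inherits(surface, "rr_surface"))
  if (!all(at_lags %in% surface$lag))
    stop2("lags %s not on the surface",
          paste(setdiff(at_lags, surface$lag), collapse = ", "))
  out <- as.data.frame(surface)[surface$lag %in% at_lags,
                                c("temperature", "lag", "rr", "lo", "hi")]
  out <- out[order(out$lag, out$temperature), ]
  rownames(out) <- NULL
  out
}

#' @export
print.rr_surface <- function(x, ...) {
  cat(sprintf("Relative-risk surface: %d temperatures x %d lags (reference %.1f degC, %d%% CI)\n",
              length(unique(x$temperature)), length(unique(x$lag)),
              attr(x, "reference"), round(100 * attr(x, "level"))))
  invisible(x)
}

#' Plot a relative-risk surface or its slices
#'
#' `type = "surface"` draws the 3-D exposure-lag-response surface
#' (perspective plot); `type = "lag"` draws RR against lag at selected
#' temperatures; `type = "temperature"` draws RR against temperature at
#' selected lags, with shaded confidence bands.
#'
#' @param x an `"rr_surface"`.
#' @param type plot flavour.
#' @param at temperatures (for `"lag"`) or lags (for `"temperature"`) to
#'   slice at; defaults to the four highest grid temperatures / lags
#'   0, 1, 2, 4.
#' @param ... passed to the underlying base-graphics call.
#' @return invisibly, `x`.
#' @export
plot.rr_surface <- function(x, type = c("surface", "lag", "temperature"),
                            at = NULL, ...) {
  type <- match.arg(type)
  temps <- sort(unique(x$temperature))
  lags <- sort(unique(x$lag))
  if (type == "surface") {
    z <- matrix(x$rr[order(x$lag, x$temperature)], length(temps), length(lags))
    graphics::persp(temps, lags, z, xlab = "Temperature (degC)", ylab = "Lag (days)",
                    zlab = "RR", theta = 230, phi = 25, col = "lightblue",
                    ticktype = "detailed", ...)
  } else if (type == "lag") {
    if (is.null(at)) at <- utils::tail(temps, 4)
    sl <- lag_slice(x, at)
    cols <- grDevices::hcl.colors(length(at), "Zissou 1")
    graphics::matplot(lags, matrix(sl$rr, length(lags)), type = "l", lty = 1,
                      col = cols, xlab = "Lag (days)", ylab = "RR", ...)
    graphics::abline(h = 1, lty = 3)
    graphics::legend("topright", legend = sprintf("%.0f degC", at),
                     col = cols, lty = 1, bty = "n")
  } else {
    if (is.null(at)) at <- intersect(c(0, 1, 2, 4), lags)
    sl <- temperature_slice(x, at)
    old <- graphics::par(mfrow = grDevices::n2mfrow(length(at)))
    on.exit(graphics::par(old))
    for (l in at) {
      d <- sl[sl$lag == l, ]
      graphics::plot(d$temperature, d$rr, type = "n",
                     ylim = range(d$lo, d$hi),
                     xlab = "Temperature (degC)", ylab = "RR",
                     main = sprintf("lag %d", l), ...)
      graphics::polygon(c(d$temperature, rev(d$temperature)),
                        c(d$lo, rev(d$hi)), col = "grey85", border = NA)
      graphics::lines(d$temperature, d$rr)
      graphics::abline(h = 1, lty = 3)
    }
  }
  invisible(x)
}

#' Write a relative-risk table as delimiter-separated text
#'
#' @param x an `"rr_surface"` or `"cum_rr"` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rr_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
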