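# brute-force Cox-de Boor B-spline basis (order = degree+1), full (with intercept)
cdb_bspline <- function(x, interior, boundary, degree) {
  kts <- c(rep(boundary[1], degree + 1), interior, rep(boundary[2], degree + 1))
  nb <- length(kts) - degree - 1
  B0 <- function(i, xx) {
    # degree-0: half-open, closed at the right end of the last interval
    if (kts[i] <= xx && xx < kts[i + 1]) return(1)
    if (xx == boundary[2] && kts[i] < kts[i + 1] && kts[i + 1] == boundary[2]) return(1)
    0
  }
  Brec <- function(i, k, xx) {
    if (k == 0) return(B0(i, xx))
    t1 <- 0
    if (kts[i + k] > kts[i])
      t1 <- (xx - kts[i]) / (kts[i + k] - kts[i]) * Brec(i, k - 1, xx)
    t2 <- 0
    if (kts[i + k + 1] > kts[i + 1])
      t2 <- (kts[i + k + 1] - xx) / (kts[i + k + 1] - kts[i + 1]) * Brec(i + 1, k - 1, xx)
    t1 + t2
  }
  out <- matrix(0, length(x), nb)
  for (r in seq_along(x)) for (i in seq_len(nb)) out[r, i] <- Brec(i, degree, x[r])
  out
}
# derivative of order d of basis function i, degree k, by recursion
cdb_deriv <- function(xx, i, k, d, kts) {
  if (d == 0) {
    # value by recursion
    if (k == 0) {
      last <- max(kts)
      if (kts[i] <= xx && xx < kts[i + 1]) return(1)
      if (xx == last && kts[i] < kts[i + 1] && kts[i + 1] == last) return(1)
      return(0)
    }
    t1 <- 0; t2 <- 0
    if (kts[i + k] > kts[i]) t1 <- (xx - kts[i])/(kts[i + k] - kts[i]) * cdb_deriv(xx, i, k - 1, 0, kts)
    if (kts[i + k + 1] > kts[i + 1]) t2 <- (kts[i + k + 1] - xx)/(kts[i + k + 1] - kts[i + 1]) * cdb_deriv(xx, i + 1, k - 1, 0, kts)
    return(t1 + t2)
  }
  t1 <- 0; t2 <- 0
  if (kts[i + k] > kts[i]) t1 <- k / (kts[i + k] - kts[i]) * cdb_deriv(xx, i, k - 1, d - 1, kts)
  if (kts[i + k + 1] > kts[i + 1]) t2 <- k / (kts[i + k + 1] - kts[i + 1]) * cdb_deriv(xx, i + 1, k - 1, d - 1, kts)
  t1 - t2
}
# natural cubic spline basis clone of splines::ns(x, knots, Boundary.knots, intercept=TRUE)
ns_oracle <- function(x, interior, boundary) {
  deg <- 3
  kts <- c(rep(boundary[1], deg + 1), interior, rep(boundary[2], deg + 1))
  nb <- length(kts) - deg - 1
  basis <- cdb_bspline(x, interior, boundary, deg)
  const <- matrix(0, 2, nb)
  for (i in seq_len(nb)) {
    const[1, i] <- cdb_deriv(boundary[1], i, deg, 2, kts)
    const[2, i] <- cdb_deriv(boundary[2], i, deg, 2, kts)
  }
  qr.const <- qr(t(const))
  as.matrix((t(qr.qty(qr.const, t(basis))))[, -(1:2), drop = FALSE])
}

# double-loop cross-basis oracle: entry (t, (i,j)) = sum_l B_i(x[t-l]) C_j(l),
# with B by Cox-de Boor and C by the natural-spline clone above
crossbasis_oracle <- function(x, spec) {
  L <- spec$max_lag
  interior_lag <- if (spec$lag_df > 2)
    unname(quantile(0:L, seq_len(spec$lag_df - 2) / (spec$lag_df - 1), type = 7))
  else numeric(0)
  C <- ns_oracle(0:L, interior_lag, c(0, L))
  Bfun <- function(xx) cdb_bspline(xx, spec$var_knots, spec$var_boundary,
                                   spec$var_degree)[, -1, drop = FALSE]
  n <- length(x)
  out <- matrix(NA_real_, n, spec$var_df * spec$lag_df)
  for (t in seq_len(n)) {
    if (t <= L) next
    for (i in seq_len(spec$var_df)) for (j in seq_len(spec$lag_df)) {
      s <- 0
      for (l in 0:L) s <- s + Bfun(x[t - l])[1, i] * C[l + 1, j]
      out[t, (i - 1) * spec$lag_df + j] <- s
    }
  }
  out
}
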