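---
title: "Methods: distributed lag non-linear case-crossover models in heatlag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distributed lag non-linear case-crossover models in heatlag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatlag)
```

## The model and its assumptions

`heatlag` estimates how daily ambient temperature affects daily mortality
counts, allowing both the shape of the temperature response and its
distribution over a window of lag days to be non-linear. Counts on day $t$
follow an overdispersed Poisson model

$$Y_t \sim \mathrm{Poisson}(\mu_t), \qquad
\log \mu_t = \alpha + \beta^\top \mathrm{CB}_t + \lambda^\top
\mathrm{Strata}_t + \eta^\top \mathrm{DOW}_t,$$

with three assumptions worth making explicit:

* **Quasi-likelihood variance.** The count variance is $\phi\,\mu_t$ with a
  single multiplicative overdispersion $\phi$, estimated as the Pearson
  statistic over residual degrees of freedom, $\hat\phi = \sum_t
  (y_t-\hat\mu_t)^2/\hat\mu_t \,/\, (n-k)$. Coefficient covariances are
  $\hat\phi$ times the inverse Fisher information, so every Wald interval
  widens by exactly $\sqrt{\hat\phi}$.
* **Confounding control by stratification.** The case-crossover strata are
  calendar year-by-month indicator columns: risk comparisons are made only
  within a month, which removes seasonality, long-term trends and any
  slowly varying confounder by design rather than by modelling. A
  time-series variant (`ts_fit()`) replaces the indicators with a natural
  cubic spline over calendar time at 7 df per year, as a cross-design check.
* **No interaction between lag days.** The cross-basis is additive over
  lags: the contribution of the temperature $x_{t-\ell}$ does not depend on
  the temperatures at other lags.

## The cross-basis

The DLNM cross-basis crosses a **quadratic B-spline** over temperature with
a **natural cubic spline** over lag:

$$\mathrm{CB}_t[(i,j)] = \sum_{\ell=0}^{L} B_i(x_{t-\ell})\, C_j(\ell),
\qquad i = 1..\mathrm{df}_{var},\; j = 1..\mathrm{df}_{lag},$$

defaulting to $L = 10$, $\mathrm{df}_{var} = \mathrm{df}_{lag} = 4$, hence
16 cross-basis coefficients. Choices that were genuinely open, and how they
were settled:

* **Temperature basis.** Degree 2 without an intercept column; with 4 df
  this places two interior knots at the 33.33rd and 66.67th percentiles of
  the observed series ("evenly distributed percentiles") and boundary knots
  at the observed range. Beyond the boundary the basis is evaluated by
  polynomial extension of the boundary pieces — predictions there are
  extrapolations and are not silently clipped; in practice the integer
  evaluation grid never leaves the observed range because the maximum is
  rounded *down*.
* **Lag basis includes its intercept.** A natural cubic spline basis
  without the intercept column has every basis function identically zero at
  the left boundary, i.e. at lag 0 — it cannot represent any same-day
  effect, which is exactly the effect these analyses care most about. The
  lag basis therefore keeps the intercept (the convention of reference DLNM
  software); with 4 df that means two interior knots between the boundary
  knots at lag 0 and lag $L$.
* **Lag knot placement.** Interior lag knots sit at equally spaced
  quantiles of the integer lags (`lag_knot_spacing = "linear"`, the
  default). Log spacing — knots equally spaced on $\log(\ell)$ between lag 1
  and lag $L$, which concentrates flexibility at short lags — is available
  as a configuration switch, and the sensitivity machinery can report both.
* **Centering is deferred to prediction.** The fitted coefficients are
  reference-free; relative risks are formed as contrasts
  $\log RR(x,\ell) = \sum_{ij} (B_i(x)-B_i(x_{ref}))\,C_j(\ell)\,\beta_{ij}$
  against the reference temperature (the series median). The contrast
  vanishes identically at $x_{ref}$, so $RR = 1$ with a zero-width interval
  there — a machine-precision identity the test suite checks on every fit.
* **Warm-up.** The first $L$ days have incomplete exposure history and are
  excluded from the likelihood rather than padded with fabricated
  pre-study temperatures. Lag windows are allowed to reach back across
  stratum boundaries: the stratum controls *when* the death occurred, the
  lag window records *what exposure preceded it*.

## Exposure aggregation and the evaluation grid

Multi-station records collapse to one daily series by population-weighted
averaging (weights normalized to sum to one; on days with partial
reporting, weights renormalize over the reporting stations — no imputation).
Percentiles use linear interpolation between order statistics
(`quantile(type = 7)`); the median of an even-length series is the mean of
the central pair. The integer evaluation grid rounds the 90th/95th/99th
percentiles *up* (they remain inside the recorded range) and the maximum
*down* (so the integer cannot leave it).

## Model selection and sensitivity

Degrees of freedom are chosen on the grid $\{4,5,6\}^2$ by
$QAIC = -2L + 2\hat\phi k$, with $QBIC = -2L + \log(n)\hat\phi k$ reported
alongside; when the two disagree, QAIC wins and the disagreement is
messaged. The sensitivity analysis varies one factor at a time — maximum
lag over $\{5, 15, 20\}$ against the base 10, and the stratum scheme over
fixed windows of 30/28/21 days against calendar months — and tabulates
$RR$ with 95% CI at the integer p90/p95/p99 temperatures, at lag 0 and
cumulated over lags, flagging variants whose point estimate leaves the base
interval.

## Numerical choices

* Fitting is iteratively reweighted least squares
  (`stats::glm.fit`, quasi-Poisson family), relative deviance tolerance
  $10^{-8}$, at most 100 iterations; non-convergence is an error, as is a
  rank-deficient design (reported with the collinear column names).
* Reference levels: first stratum and Monday. Relative risks are invariant
  to both choices.
* Strata whose total count is zero carry no information and are dropped
  with a warning.
* The 95% normal quantile is computed (`qnorm(0.975)`), not hard-coded.
* Per-category analyses keep days with zero deaths as observed zeros — the
  Poisson likelihood handles them naturally — and the aggregated fit uses
  the category-summed counts.

## The synthetic-data generator

Because no public deposit exists for registry mortality and station
networks of this kind, validation runs on synthetic studies with known
truth. The generator emulates:

* **Climate:** a sinusoidal seasonal cycle (peak mid-year) around an annual
  mean of 19 degC with amplitude 8 degC, station offsets (sd 1 degC) and
  daily noise (sd 1.8 degC) — a subtropical island profile whose summer
  daily means average 26-27 degC and whose population-weighted medians and
  upper percentiles land near 19-20 and 27-29 degC. `t_max`/`t_min` add and
  subtract a non-negative diurnal excursion (mean 5 degC), so the record
  ordering `t_min <= t_mean <= t_max` holds row-wise. Years are 365 days;
  leap days are an ingestion concern, not a simulation one.
* **Mortality:** a baseline of 13,889/2,555 ≈ 5.4 deaths/day split across
  the five ICD-10 circulatory groups in registry-scale proportions
  (1220 : 4773 : 4595 : 2893 : 408), a winter-peaking seasonal cycle of
  log-amplitude 0.15, small day-of-week offsets (weekends about 2-3%
  lower), and overdispersion 1.3 via a negative binomial parameterized so
  the variance is exactly $\phi\mu$. The within-week and seasonal structure
  of the emulated registry is not documented anywhere, so these defaults
  are deliberate, realistic placeholders — free parameters of the
  generator, not facts about any population.
* **The injected surface:** `rr_surface_spec()` supports a
  threshold-linear ("hockey-stick") and a quadratic-above-reference shape,
  both exactly zero at and below their reference for every lag, scaled by a
  per-lag coefficient vector. This emulates a pure heat effect with
  short-lag structure.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: spatially structured weather (all stations
share one cycle plus iid noise), humidity, heat waves as autocorrelated
episodes, age structure, influenza winters, or reporting artifacts beyond
the day-of-week cycle.

## Problem sizes used in validation

The test suite exercises study scale — 7 years × 365 days, ~5.4 deaths/day —
for the recovery, calibration and sensitivity checks: 50 replicates for
coverage of an injected lag-0 effect at the 95th-percentile temperature,
200 replicates for null coverage of $RR = 1$ (nominal 95%), and 6
replicated sensitivity sweeps; smaller 1-4 year studies back the
per-module checks, and 30-60-day toys back the exact oracle comparisons
(brute-force Cox-de Boor cross-basis to $10^{-10}$; an independent BFGS
maximizer of the same Poisson likelihood to $10^{-6}$). The reproduction
script (`scripts/acceptance.R`) re-runs the pipeline at study scale with a
100-replicate null-calibration study.

## Known limitations

* Quadratic B-spline extrapolation beyond the observed temperature range is
  polynomial and can behave erratically; the package documents rather than
  forbids it, and the default evaluation grid avoids it.
* The threshold-linear truth used in recovery tests has a kink the smooth
  quadratic basis cannot represent exactly; point estimates near the
  threshold are mildly attenuated, which the interval-coverage criteria
  absorb.
* Quasi-likelihood treats overdispersion as constant over time; bursty
  overdispersion (epidemics, heat waves) would violate this.
* The case-crossover design removes monthly-scale confounding but cannot
  separate effects of consecutive hot days from the lag structure itself
  (additivity over lags is assumed).
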