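---
title: "Two-stage DLNM analysis of temperature-mortality associations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage DLNM analysis of temperature-mortality associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Daily mean temperature affects daily mortality non-linearly (risk rises at
both cold and hot extremes) and with delay (cold effects stretch over weeks,
heat effects are immediate). Multi-city time-series studies estimate this
association per city, pool the city curves, and translate the pooled
association into an attributable burden: what share of observed deaths would
not have occurred had every day been at the optimum temperature.

`tempmort` implements the complete two-stage workflow on daily city panels
(deaths, temperature, humidity, PM2.5, O3), together with a synthetic
multi-city generator with a *known* exposure-lag-response surface, so every
stage can be validated end to end without access to any mortality registry.

# Stage one: city-level distributed lag non-linear model

For city $i$, daily death counts $Y_{it}$ follow a (quasi-)Poisson
log-linear model

$$\log E[Y_{it}] = \alpha + cb(\text{Temp}_{it}) + ns(\text{RH}, 4) +
ns(\text{PM}_{2.5}, 4) + ns(\text{O}_3, 4) + ns(t, 8 \cdot \text{year}) +
\text{DOW},$$

where $cb(\cdot)$ is a cross-basis: the tensor product of

* an **exposure basis**: quadratic B-spline with interior knots at the city's
  25th/50th/75th temperature percentiles, boundary knots at the city min/max
  ($v_x = 5$ columns);
* a **lag basis** over lags $0..L$ (default $L = 25$ days): natural cubic
  spline *with* intercept and three interior knots equally spaced on the log
  lag scale, $L^{j/4}$ for $j = 1, 2, 3$ ($v_l = 5$ columns).

Column $(j, k)$ of the cross-basis at day $t$ is
$\sum_{l=0}^{L} R_j(x_{t-l})\, C_k(l)$, stored exposure-major (all lag
columns of exposure function 1 first). The first $L$ days lack a complete
lag history and are dropped from the likelihood rather than zero-padded;
the synthetic generator emits $L$ burn-in days so this costs nothing.

Fitting uses iteratively reweighted least squares (`stats::glm.fit`,
deviance tolerance `1e-9`, at most 100 iterations). `family = "poisson"` is
the default; `"quasipoisson"` gives identical point estimates and rescales
the covariance by the Pearson dispersion. Rank deficiency is an error naming
the collinear columns. Strata with mean daily deaths below 3 trigger a
warning (BLUP shrinkage at stage two is the intended remedy, not a minimum
count exclusion).

The fitted cross-basis coefficients are reduced to the **overall cumulative
exposure-response**, the curve obtained by summing lag contributions over
all lags: on the coefficient scale this is the exact linear map
$M = I_{v_x} \otimes s^{\top}$ with $s$ the lag basis summed over integer
lags. The reduction and both prediction paths (overall curve and
lag-specific curve at a fixed temperature) were verified during development
to agree with the established DLNM reference implementation to machine
precision; the shipped test suite checks them against independent
brute-force oracles instead.

# Stage two: pooling, BLUP, minimum mortality temperature

Per-city reduced coefficients $\hat\theta_i$ (with covariances $S_i$) are
pooled under the multivariate random-effects model
$\hat\theta_i \sim N(\mu, \Psi + S_i)$. $\Psi$ is estimated by REML on the
profiled restricted likelihood with an analytic gradient, parameterized by
its Cholesky factor so it remains positive semi-definite; a
method-of-moments estimate (sample covariance of $\hat\theta_i$ minus the
average $S_i$, eigenvalue-clipped) is the starting value and the fallback if
the optimizer fails. Curves are pooled on the coefficient scale: the
percentile-anchored knots make coefficients comparable across cities, at
the cost that a common *temperature* optimum maps to different percentiles
in different climates (see "what a green test establishes" below).

City-specific curves are shrunk toward the pool:
$\text{blup}_i = \hat\mu + \Psi(\Psi + S_i)^{-1}(\hat\theta_i - \hat\mu)$.
For the BLUP covariance the conditional variance
$\Psi - \Psi(\Psi + S_i)^{-1}\Psi$ alone collapses to zero whenever
$\hat\Psi = 0$, which would give a homogeneous panel degenerate Monte Carlo
intervals; we therefore add the propagated fixed-effects uncertainty
$(I - B_i)\,\widehat{var}(\hat\mu)\,(I - B_i)^{\top}$ with
$B_i = \Psi(\Psi + S_i)^{-1}$, so a fully shrunk city inherits the pooled
curve *and* its uncertainty.

The **minimum mortality temperature** (MMT) and percentile (MMP) are found
by evaluating each city's BLUP curve on the city's own temperature
percentile grid (0.1-percentile resolution, searched between the 1st and
99th percentiles) and taking the argmin; exact ties break toward the median
percentile. The MMT is the reference for all relative risks and for
attribution.

# Attributable burden

Attribution is **backward** and operates on the overall cumulative curve:
for day $t$, $b_t = f(x_t) - f(\text{MMT})$ and the attributable deaths are
$AN_t = Y_t\,(1 - e^{-b_t})$. This is the standard simplification when only
reduced/BLUP coefficients exist at stage two: the cumulative curve applied
to the day's own exposure stands in for the sum over its 25-day exposure
history, which is exact for sustained exposures and a close approximation
for autocorrelated temperature series. The first $L$ days are excluded so
every attributed day has the full history the cumulative curve summarizes.
Full forward attribution from the lag surface is intentionally out of
scope; both the BLUP-based default and a pooled-curve alternative are
available (`mmt_source` in `run_config()`).

Each day's $AN_t$ belongs to exactly one of four components by its own mean
temperature — extreme cold (below the city's 1st percentile), moderate cold
(1st percentile to MMT), moderate heat (MMT to 99th), extreme heat (above
the 99th) — so cold + heat = total and extreme + moderate = side hold
*exactly*, for point estimates and for every Monte Carlo draw. City
aggregation sums the four leaf components across cities first and derives
cold/heat/total from the sums, keeping the identities exact in floating
point.

**Empirical confidence intervals** come from Monte Carlo simulation: 1000
draws (default) of the coefficient vector from $N(\hat\theta,
\widehat{var})$, recomputing all component ANs per draw with the MMT held
fixed at its point estimate (re-estimating it per draw would change the
estimand), and taking empirical 2.5/97.5 percentiles. Pooled intervals sum
per-draw ANs across cities at a shared draw index. With a zero covariance
the interval collapses to the point estimate, by construction.

# The synthetic world

The generator emulates a humid subtropical basin: per-city temperature is a
sinusoid (annual minimum mid-January) plus stationary AR(1) anomalies, with
the four reference-panel climates matching the published city means (16.8,
18.9, 16.3, 21.6 degrees C) and seasonal swings chosen to reproduce the
published min/max ranges. Baseline mortality is log-linear: a winter excess
(amplitude 0.1 on the log scale), a mild centred drift (0.01/year), and
day-of-week offsets summing to zero; mean daily deaths for the reference
cities (242, 58, 47, 18) span the published range. Humidity is clamped
Gaussian; PM2.5 and O3 are log-normal with natural-scale moments taken from
the published descriptive table. Confounders carry **no** mortality effect
in the generator, which is itself a testable statement (removing their
adjustment must not move the attributable fraction).

The true exposure-lag-response surface is a piecewise-quadratic U with its
minimum at 25.0 degrees C — roughly the 80th percentile in these climates,
matching the high minimum-mortality percentiles reported in basin
populations. The cold limb is the steeper side in total rise (RR about 1.5
at 18 degrees below the MMT vs about 1.15 at 7 degrees above), and with
about 80% of days below the MMT the burden is strongly cold-dominant. Heat
effect is distributed geometrically over lags 0-3 (immediate, gone within
days); cold decays slowly (ratio 0.85/day) over the full 25-day window.
Counts are Poisson by default; an `overdispersion` knob adds a gamma
frailty for robustness tests.

What the generator does **not** emulate: spatial correlation between
cities, humidity-temperature coupling, pollution episodes correlated with
weather, cause-of-death structure, demographic drift. A green test
establishes that the estimators recover a known surface of realistic shape
under Poisson sampling and smooth confounding — not that any particular
registry estimate is correct.

Determinism: every sampling function takes a seed; the pipeline derives
named child seeds from the master seed (`child_seed(master, stream,
index)`, a fixed integer mix below $2^{31}$) so adding a stage never
perturbs another stage's draws, and two runs with one master seed produce
byte-identical output tables.

# Numerical choices and degenerate inputs

* Quantiles everywhere (knots, percentile tables, eCIs) use the type-7
  rule, fixed for reproducibility.
* B-spline evaluation outside the boundary knots is an error during
  fitting; prediction grids may extrapolate linearly (value plus boundary
  derivative). Natural cubic bases are linear beyond their boundaries by
  construction.
* Time-spline df = `round(df_per_year * n/365.25)`, interior knots at
  equally spaced quantiles of the day index.
* A missing temperature invalidates its own day plus the following $L$
  days; missing outcomes or confounders drop only their own day. More than
  20% unusable rows warns; more than 50% errors.
* With one city, pooling degenerates to a pass-through ($\Psi = 0$); with
  $\hat\Psi = 0$, every BLUP equals the pooled vector exactly.
* MMT at a search boundary (1st/99th percentile) is returned as-is — a
  monotone curve legitimately clamps.
* Covariance matrices are symmetrized and checked PSD to `1e-8` before
  Monte Carlo draws; draws use an eigendecomposition square root so
  degenerate (zero) covariances are handled exactly.

# Known limitations

* The MMT is an argmin of a flat-bottomed curve: its sampling error scales
  like $\sqrt{2\,\varepsilon / f''}$ for curve error $\varepsilon$, so with
  realistic curvature a well-estimated curve (log-RR RMSE around 0.05)
  still leaves city MMTs uncertain by 1-3 degrees C. Burden estimates are
  much more stable than the MMT itself.
* Because pooling happens on percentile-anchored coefficients, cities with
  very different climates shrink toward a common *percentile* shape; a
  shared temperature optimum is then recovered with a climate-dependent
  bias. This mirrors the behaviour of the published two-stage framework.
* Backward attribution with the reduced curve ignores within-window
  temperature variation; the day-level error is second order but not zero.
* The attributable fraction referenced at an *estimated* MMT is positively
  biased in small samples (argmin selection); null-calibration coverage of
  zero is therefore slightly below nominal, which the acceptance suite
  quantifies (at least 88/100 nominal-95% intervals cover zero in the null
  world).
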