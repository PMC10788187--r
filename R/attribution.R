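#' Temperature percentile table at 0.1-percentile resolution
#'
#' @param x temperature observations (NAs dropped).
#' @return data.frame with `percentile` (0 to 100 by 0.1) and `temp`
#'   (type-7 quantiles).
#' @export
temp_percentile_table <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stopf("no non-missing temperatures")
  p <- seq(0, 100, by = 0.1)
  data.frame(percentile = p,
             temp = unname(stats::quantile(x, p / 100, type = 7)))
}

#' Find the minimum mortality temperature and percentile
#'
#' Evaluates the overall cumulative log-RR curve at every grid percentile's
#' temperature between the search bounds (default 1st-99th) and returns the
#' minimizing percentile/temperature. Ties within numerical tolerance are
#' broken toward the median percentile (50).
#'
#' @param coef length-vx curve coefficients (e.g. a BLUP).
#' @param exposure_spec the exposure [basis_spec()].
#' @param percentile_table as from [temp_percentile_table()].
#' @param range percentile search bounds.
#' @return object of class `mmt_result`: `mmt`, `mmp`, `log_rr_at_mmt`
#'   (uncentered scale), plus the searched grid bounds.
#' @export
find_mmt <- function(coef, exposure_spec, percentile_table,
                     range = c(1, 99)) {
  pt <- percentile_table
  sel <- pt$percentile >= range[1] & pt$percentile <= range[2]
  if (!any(sel)) stopf("percentile table does not cover the search range")
  grid <- pt[sel, ]
  B <- evaluate_basis(grid$temp, exposure_spec, extrapolate = TRUE)
  lr <- drop(B %*% coef)
  if (any(!is.finite(lr))) stopf("non-finite curve values in MMT search")
  ties <- which(lr <= min(lr) + 1e-12)
  pick <- ties[which.min(abs(grid$percentile[ties] - 50))]
  structure(list(mmt = grid$temp[pick], mmp = grid$percentile[pick],
                 log_rr_at_mmt = lr[pick], range = range),
            class = "mmt_result")
}

#' Four-level temperature cutoffs for a city
#'
#' Extreme cold: below the 1st percentile; moderate cold: 1st percentile to
#' MMT; moderate heat: MMT to 99th percentile; extreme heat: above the 99th.
#'
#' @param percentile_table as from [temp_percentile_table()].
#' @param mmt the city's minimum mortality temperature.
#' @return list with `p1`, `mmt`, `p99`.
#' @export
temperature_levels <- function(percentile_table, mmt) {
  p1 <- percentile_table$temp[match(1, percentile_table$percentile)]
  p99 <- percentile_table$temp[match(99, percentile_table$percentile)]
  if (p1 >= p99) stopf("degenerate temperature distribution (p1 >= p99)")
  list(p1 = p1, mmt = mmt, p99 = p99)
}

# component labels, leaf-to-derived
.components <- c("extreme_cold", "moderate_cold", "moderate_heat",
                 "extreme_heat", "cold", "heat", "total")

classify_days <- function(temp, levels) {
  side <- ifelse(temp < levels$mmt, "cold", "heat")
  comp <- ifelse(side == "cold",
                 ifelse(temp < levels$p1, "extreme_cold", "moderate_cold"),
                 ifelse(temp > levels$p99, "extreme_heat", "moderate_heat"))
  factor(comp, levels = .components[1:4])
}

#' Daily attributable deaths under the backward perspective
#'
#' For day t the cumulative log-RR of its exposure relative to the MMT is
#' read off the reduced overall cumulative curve,
#' `b_t = f(x_t) - f(mmt)`, and the attributable number is
#' `AN_t = deaths_t * (1 - exp(-b_t))`. The first `max_lag` days lack the
#' full lag history the cumulative curve summarizes and are excluded.
#'
#' @param coef curve coefficients (BLUP by default in the pipeline).
#' @param exposure_spec exposure [basis_spec()].
#' @param temps daily mean temperatures.
#' @param deaths daily death counts (same length).
#' @param mmt reference temperature; must lie within the observed range.
#' @param max_lag number of leading days to exclude.
#' @return data.frame with `day`, `temp`, `deaths`, `log_rr`, `an`.
#' @export
attribute_daily <- function(coef, exposure_spec, temps, deaths, mmt,
                            max_lag = 0L) {
  stopifnot(length(temps) == length(deaths))
  rng <- range(temps, na.rm = TRUE)
  if (mmt < rng[1] || mmt > rng[2])
    stopf("mmt (%g) outside the observed temperature range [%g, %g]",
          mmt, rng[1], rng[2])
  idx <- seq_along(temps) > max_lag
  B <- evaluate_basis(temps[idx], exposure_spec, extrapolate = TRUE)
  b0 <- drop(evaluate_basis(mmt, exposure_spec))
  lr <- drop(sweep(B, 2, b0) %*% coef)
  an <- deaths[idx] * (1 - exp(-lr))
  data.frame(day = which(idx), temp = temps[idx], deaths = deaths[idx],
             log_rr = lr, an = an)
}

#' Decompose daily attributable deaths into temperature components
#'
#' Each attributed day contributes to exactly one of the four leaf
#' components by its own mean temperature; cold/heat and the total are the
#' corresponding sums, so conservation is exact by construction.
#'
#' @param daily result of [attribute_daily()].
#' @param levels a [temperature_levels()] list.
#' @return list with named vectors `an` and `af` (%) over components
#'   `extreme_cold, moderate_cold, moderate_heat, extreme_heat, cold, heat,
#'   total`, and `deaths` (total observed deaths over attributed days).
#' @export
decompose_attribution <- function(daily, levels) {
  comp <- classify_days(daily$temp, levels)
  an4 <- vapply(split(daily$an, comp), sum, 0)
  an <- c(an4,
          cold = unname(an4["extreme_cold"] + an4["moderate_cold"]),
          heat = unname(an4["extreme_heat"] + an4["moderate_heat"]))
  an <- c(an, total = unname(an["cold"] + an["heat"]))
  deaths <- sum(daily$deaths)
  list(an = an[.components], af = 100 * an[.components] / deaths,
       deaths = deaths)
}

# Per-draw leaf-component AN matrix: draws (n_sim x vx) against the
# day-level difference basis; returns n_sim x 4 matrix.
an_draws_matrix <- function(draws, exposure_spec, daily, levels, mmt) {
  B <- evaluate_basis(daily$temp, exposure_spec, extrapolate = TRUE)
  b0 <- drop(evaluate_basis(mmt, exposure_spec))
  D <- sweep(B, 2, b0) # n_days x vx
  lr <- D %*% t(draws) # n_days x n_sim
  an_t <- daily$deaths * (1 - exp(-lr))
  comp <- classify_days(daily$temp, levels)
  out <- matrix(0, nrow(draws), 4,
                dimnames = list(NULL, .components[1:4]))
  for (cmp in .components[1:4]) {
    sel <- comp == cmp
    if (any(sel)) out[, cmp] <- colSums(an_t[sel, , drop = FALSE])
  }
  out
}

#' Monte Carlo empirical confidence intervals
#'
#' Draws coefficient vectors from `N(coef, vcov)` and recomputes a
#' user-supplied statistic per draw; the eCI is the empirical 2.5th/97.5th
#' percentile. The MMT (and any other plug-in) should be held fixed inside
#' `fun` so the estimand does not change across draws.
#'
#' @param coef,vcov coefficient mean and covariance (vcov is symmetrized and
#'   must be PSD within 1e-8).
#' @param fun function(coef_draw) returning a named numeric vector.
#' @param n_sim number of draws (>= 100).
#' @param seed integer seed; draws are deterministic given it.
#' @param level confidence level.
#' @return list with `draws` (n_sim x length(fun(coef))), `low`, `high`.
#' @export
monte_carlo_eci <- function(coef, vcov, fun, n_sim = 1000L, seed = 1L,
                            level = 0.95) {
  if (n_sim < 100) stopf("`n_sim` must be >= 100")
  draws <- with_seed(seed, rmvn(n_sim, coef, vcov))
  vals <- apply(draws, 1, fun)
  vals <- if (is.matrix(vals)) t(vals) else
    matrix(vals, ncol = 1, dimnames = list(NULL, names(fun(coef))))
  a <- (1 - level) / 2
  list(draws = vals,
       low = apply(vals, 2, stats::quantile, probs = a, type = 7),
       high = apply(vals, 2, stats::quantile, probs = 1 - a, type = 7))
}

#' Full attribution for one city and stratum
#'
#' Point estimates and Monte Carlo eCIs for attributable numbers and
#' fractions in all seven components, using a single coefficient curve
#' (BLUP or pooled) and the city's own MMT, held fixed across draws.
#'
#' @param curve list with `coef`, `vcov`, `exposure_spec` (a `blup_set`
#'   element, a `reduced_fit`, or a pooled model repackaged).
#' @param series the `city_series` attributed.
#' @param stratum outcome stratum.
#' @param mmt_result a [find_mmt()] result for this city.
#' @param levels a [temperature_levels()] list.
#' @param max_lag leading days excluded (lag history length).
#' @param n_sim Monte Carlo draws.
#' @param seed integer seed.
#' @return object of class `attribution_result`: `city_id`, `stratum`,
#'   `mmp`, `mmt`, `deaths`, `table` (data.frame component/an/af with eCIs),
#'   `an_draws` (n_sim x 4 leaf components, for pooled aggregation).
#' @export
attribute_city <- function(curve, series, stratum = "total", mmt_result,
                           levels, max_lag = 25L, n_sim = 1000L, seed = 1L) {
  daily <- attribute_daily(curve$coef, curve$exposure_spec,
                           series$temp_mean, series$deaths[[stratum]],
                           mmt_result$mmt, max_lag = max_lag)
  point <- decompose_attribution(daily, levels)
  draws <- with_seed(seed, rmvn(n_sim, curve$coef, curve$vcov))
  anmat <- an_draws_matrix(draws, curve$exposure_spec, daily, levels,
                           mmt_result$mmt)
  build_attribution_result(series$city_id, stratum, mmt_result, point,
                           anmat)
}

# assemble the 7-component table from the point estimates and the n_sim x 4
# leaf-component draw matrix
build_attribution_result <- function(city_id, stratum, mmt_result, point,
                                     anmat) {
  full <- cbind(anmat,
                cold = anmat[, "extreme_cold"] + anmat[, "moderate_cold"],
                heat = anmat[, "extreme_heat"] + anmat[, "moderate_heat"])
  full <- cbind(full, total = full[, "cold"] + full[, "heat"])
  qs <- apply(full, 2, stats::quantile, probs = c(0.025, 0.975), type = 7)
  tab <- data.frame(component = .components,
                    an = unname(point$an[.components]),
                    an_low = qs[1, .components],
                    an_high = qs[2, .components],
                    af = unname(point$af[.components]),
                    af_low = 100 * qs[1, .components] / point$deaths,
                    af_high = 100 * qs[2, .components] / point$deaths,
                    row.names = NULL)
  structure(list(city_id = city_id, stratum = stratum,
                 mmp = if (is.null(mmt_result)) NA_real_ else mmt_result$mmp,
                 mmt = if (is.null(mmt_result)) NA_real_ else mmt_result$mmt,
                 deaths = point$deaths, table = tab, an_draws = anmat),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("<attribution_result> %s/%s: MMT %.1f (MMP %.1f), %d deaths\n",
              x$city_id, x$stratum, x$mmt, x$mmp, x$deaths))
  print(x$table[x$table$component %in% c("total", "cold", "heat"), ],
        row.names = FALSE)
  invisible(x)
}

#' Aggregate per-city attribution results
#'
#' Pooled attributable numbers are sums over cities; pooled fractions divide
#' by the summed observed deaths. The pooled eCI sums per-draw ANs across
#' cities at a shared draw index before taking percentiles, preserving the
#' conservation identities draw by draw.
#'
#' @param results list of [attribute_city()] results (same stratum).
#' @return an `attribution_result` with `city_id = "total"`.
#' @export
aggregate_cities <- function(results) {
  stopifnot(length(results) >= 1)
  ns <- vapply(results, function(r) nrow(r$an_draws), 0L)
  if (length(unique(ns)) != 1)
    stopf("cities were simulated with different n_sim (%s)",
          paste(unique(ns), collapse = ", "))
  anmat <- Reduce(`+`, lapply(results, `[[`, "an_draws"))
  deaths <- sum(vapply(results, `[[`, 0, "deaths"))
  # aggregate the four leaf components, then derive cold/heat/total, so the
  # conservation identities stay exact in floating point
  an4 <- Reduce(`+`, lapply(results, function(r) {
    v <- r$table$an; names(v) <- r$table$component; v[.components[1:4]]
  }))
  an <- c(an4,
          cold = unname(an4["extreme_cold"] + an4["moderate_cold"]),
          heat = unname(an4["extreme_heat"] + an4["moderate_heat"]))
  an <- c(an, total = unname(an["cold"] + an["heat"]))
  point <- list(an = an[.components], af = 100 * an[.components] / deaths,
                deaths = deaths)
  out <- build_attribution_result("total", results[[1]]$stratum, NULL,
                                  point, anmat)
  out
}
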