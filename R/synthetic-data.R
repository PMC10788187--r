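#' City climate specification for the synthetic generator
#'
#' Describes a city's temperature climate (annual cycle plus AR(1) noise) and
#' the marginal distributions of the confounders. Defaults emulate a humid
#' subtropical basin climate: annual mean around 18 degrees C with a seasonal
#' swing of +/- 8, high humidity, moderate PM2.5 and O3 levels.
#'
#' @param city_id character label.
#' @param n_years number of calendar years of data (>= 1).
#' @param annual_mean_temp annual mean temperature, degrees C.
#' @param seasonal_amplitude half-range of the seasonal cycle, degrees C
#'   (>= 0); the annual minimum falls in mid-January.
#' @param ar_coefficient AR(1) coefficient of the daily anomaly, |rho| < 1.
#' @param daily_sd marginal standard deviation of the daily anomaly,
#'   degrees C (> 0).
#' @param rh_mean,rh_sd mean and sd of relative humidity, percent (clamped
#'   to \[0, 100\]).
#' @param pm25_mean,pm25_sd mean and sd of PM2.5 on the natural scale,
#'   ug/m3; values are drawn log-normally with these moments.
#' @param o3_mean,o3_sd same for 8-h mean O3, ug/m3.
#' @param start_year first calendar year of the series.
#' @return object of class `city_climate_spec`.
#' @export
city_climate_spec <- function(city_id, n_years = 6L,
                              annual_mean_temp = 18.3,
                              seasonal_amplitude = 8,
                              ar_coefficient = 0.7, daily_sd = 2.5,
                              rh_mean = 72.4, rh_sd = 10,
                              pm25_mean = 41.6, pm25_sd = 25,
                              o3_mean = 85.4, o3_sd = 35,
                              start_year = 2016L) {
  if (n_years < 1) stopf("`n_years` must be >= 1")
  if (seasonal_amplitude < 0) stopf("`seasonal_amplitude` must be >= 0")
  if (abs(ar_coefficient) >= 1) stopf("`ar_coefficient` must satisfy |rho| < 1")
  if (daily_sd < 0) stopf("`daily_sd` must be >= 0")
  for (nm in c("rh_sd", "pm25_mean", "pm25_sd", "o3_mean", "o3_sd")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0) stopf("`%s` must be > 0", nm)
  }
  structure(list(city_id = as.character(city_id), n_years = as.integer(n_years),
                 annual_mean_temp = annual_mean_temp,
                 seasonal_amplitude = seasonal_amplitude,
                 ar_coefficient = ar_coefficient, daily_sd = daily_sd,
                 rh_mean = rh_mean, rh_sd = rh_sd,
                 pm25_mean = pm25_mean, pm25_sd = pm25_sd,
                 o3_mean = o3_mean, o3_sd = o3_sd,
                 start_year = as.integer(start_year)),
            class = "city_climate_spec")
}

climate_dates <- function(spec, burn_in = 0L) {
  start <- as.Date(sprintf("%d-01-01", spec$start_year))
  end <- as.Date(sprintf("%d-12-31", spec$start_year + spec$n_years - 1L))
  seq(start - burn_in, end, by = "day")
}

seasonal_temp <- function(spec, dates) {
  doy <- as.POSIXlt(dates)$yday + 1
  # annual minimum mid-January (doy 15)
  spec$annual_mean_temp -
    spec$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25)
}

#' Simulate a daily mean temperature series
#'
#' Sinusoidal annual cycle plus stationary AR(1) Gaussian anomalies with
#' marginal standard deviation `daily_sd`. Deterministic given `seed`.
#'
#' @param spec a [city_climate_spec()].
#' @param seed integer seed.
#' @param burn_in extra leading days to generate (used internally to give
#'   day 1 of an emitted series a full lag history).
#' @return numeric vector, one temperature per calendar day.
#' @export
simulate_temperature <- function(spec, seed, burn_in = 0L) {
  stopifnot(inherits(spec, "city_climate_spec"))
  dates <- climate_dates(spec, burn_in)
  n <- length(dates)
  mu <- seasonal_temp(spec, dates)
  with_seed(seed, {
    rho <- spec$ar_coefficient
    e <- numeric(n)
    if (spec$daily_sd > 0) {
      innov_sd <- spec$daily_sd * sqrt(1 - rho^2)
      e[1] <- stats::rnorm(1, 0, spec$daily_sd)
      z <- stats::rnorm(n - 1, 0, innov_sd)
      for (t in seq_len(n - 1)) e[t + 1] <- rho * e[t] + z[t]
    }
    mu + e
  })
}

#' Ground-truth exposure-lag-response surface
#'
#' Wraps a cumulative exposure-response curve (log RR relative to its own
#' minimum, the true MMT) and per-side lag-share vectors distributing that
#' cumulative effect over lags 0..L. Shares sum to one on each side so the
#' cumulative effect of a sustained exposure equals `curve(x)` exactly.
#'
#' @param curve function(temp) -> cumulative log RR, with
#'   `curve(true_mmt) = 0` and `curve >= 0`.
#' @param cold_shares,heat_shares length L+1 non-negative vectors summing
#'   to 1: the share of the cumulative effect realized at each lag for
#'   exposures below / at-or-above the MMT.
#' @param true_mmt the temperature at which `curve` attains its minimum.
#' @return object of class `risk_surface` with `max_lag = length(shares) - 1`.
#' @export
risk_surface <- function(curve, cold_shares, heat_shares, true_mmt) {
  stopifnot(is.function(curve))
  if (length(cold_shares) != length(heat_shares))
    stopf("cold and heat share vectors must have equal length")
  for (nm in c("cold_shares", "heat_shares")) {
    s <- get(nm)
    if (any(s < 0)) stopf("`%s` must be non-negative", nm)
    if (abs(sum(s) - 1) > 1e-12) stopf("`%s` must sum to 1", nm)
  }
  if (abs(curve(true_mmt)) > 1e-12)
    stopf("`curve(true_mmt)` must be 0")
  structure(list(curve = curve, cold_shares = cold_shares,
                 heat_shares = heat_shares, true_mmt = true_mmt,
                 max_lag = length(cold_shares) - 1L),
            class = "risk_surface")
}

#' Default U-shaped risk surface
#'
#' Piecewise-quadratic cumulative curve centred at `mmt` with a steeper cold
#' limb: the cold side rises to a higher relative risk at its extreme (about
#' 1.5 at 18 degrees below the MMT) than the heat side (about 1.15 at 7
#' degrees above), and in a climate whose 75-85th percentile sits near the
#' MMT the cold side also spans far more days, so the cold burden dominates.
#' Heat lag shares decay geometrically over lags 0-3 (immediate effect);
#' cold shares decay slowly over lags 0-L (prolonged effect).
#'
#' @param mmt true minimum-mortality temperature, degrees C.
#' @param cold_scale,heat_scale log-RR per (10 degrees C)^2 on each limb.
#' @param max_lag maximum lag L.
#' @param heat_span lags carrying heat effect (0..heat_span).
#' @param heat_decay,cold_decay geometric decay ratios of the lag shares.
#' @return a [risk_surface()].
#' @export
default_risk_surface <- function(mmt = 25, cold_scale = 0.12,
                                 heat_scale = 0.28, max_lag = 25L,
                                 heat_span = 3L, heat_decay = 0.35,
                                 cold_decay = 0.85) {
  curve <- function(x) {
    d <- (x - mmt) / 10
    ifelse(x < mmt, cold_scale * d^2, heat_scale * d^2)
  }
  heat <- numeric(max_lag + 1L)
  heat[seq_len(heat_span + 1L)] <- heat_decay^(0:heat_span)
  heat <- heat / sum(heat)
  cold <- cold_decay^(0:max_lag)
  cold <- cold / sum(cold)
  risk_surface(curve, cold, heat, mmt)
}

#' Null (flat) risk surface
#' @param max_lag maximum lag L.
#' @return a [risk_surface()] with zero effect at every temperature.
#' @export
null_risk_surface <- function(max_lag = 25L) {
  shares <- rep(1 / (max_lag + 1), max_lag + 1L)
  risk_surface(function(x) rep(0, length(x)), shares, shares, true_mmt = 0)
}

#' Baseline mortality process specification
#'
#' Log-scale baseline: `log(mean_daily_deaths)` plus a winter-peaking
#' seasonal component, a linear long-term drift, and day-of-week offsets.
#'
#' @param mean_daily_deaths expected deaths/day at the seasonal midpoint.
#' @param seasonal_amplitude log-scale amplitude of the winter mortality
#'   excess (peak mid-January).
#' @param trend_slope log-scale linear drift per year.
#' @param dow_effects length-7 log-scale offsets (Mon..Sun), summing to 0.
#' @return object of class `baseline_spec`.
#' @export
baseline_mortality_spec <- function(mean_daily_deaths = 50,
                                    seasonal_amplitude = 0.1,
                                    trend_slope = 0.01,
                                    dow_effects = c(0.00, -0.01, -0.01, -0.01,
                                                    0.00, 0.01, 0.02)) {
  if (mean_daily_deaths <= 0) stopf("`mean_daily_deaths` must be > 0")
  if (length(dow_effects) != 7L) stopf("`dow_effects` must have length 7")
  if (abs(sum(dow_effects)) > 1e-10) stopf("`dow_effects` must sum to 0")
  structure(list(mean_daily_deaths = mean_daily_deaths,
                 seasonal_amplitude = seasonal_amplitude,
                 trend_slope = trend_slope, dow_effects = dow_effects),
            class = "baseline_spec")
}

baseline_log_rate <- function(baseline, dates) {
  doy <- as.POSIXlt(dates)$yday + 1
  dow <- as.integer(format(dates, "%u")) # 1 = Monday
  # drift centered on the series midpoint so mean_daily_deaths is the
  # series-average baseline rate
  yrs <- as.numeric(dates - dates[1]) / 365.25
  yrs <- yrs - mean(yrs)
  log(baseline$mean_daily_deaths) +
    baseline$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25) +
    baseline$trend_slope * yrs +
    baseline$dow_effects[dow]
}

# Sum over lags of curve(x[t-l]) * share_l, using the side of the lagged
# exposure to pick the share vector. Vector x includes the burn-in; returns
# the contribution for positions (L+1)..length(x).
lagged_risk_contribution <- function(x, risk) {
  L <- risk$max_lag
  n <- length(x)
  cv <- risk$curve(x)
  out <- numeric(n - L)
  idx <- (L + 1L):n
  for (l in 0:L) {
    xi <- idx - l
    sh <- ifelse(x[xi] < risk$true_mmt, risk$cold_shares[l + 1L],
                 risk$heat_shares[l + 1L])
    out <- out + cv[xi] * sh
  }
  out
}

#' Simulate one city's daily mortality series
#'
#' Deaths are Poisson with log-rate = baseline + the lagged contribution of
#' the true exposure-lag-response surface. L extra leading days are generated
#' as burn-in so every emitted day has a full lag history. Stratum counts are
#' drawn multinomially from the daily total (so strata always sum to the
#' total); if `strata_risk` supplies a per-stratum surface, strata are drawn
#' as independent Poissons with their own surfaces and the total is their sum.
#'
#' @param climate a [city_climate_spec()].
#' @param risk a [risk_surface()].
#' @param baseline a [baseline_mortality_spec()].
#' @param strata_weights named probabilities summing to 1 (e.g.
#'   `c(male = 0.52, female = 0.48)`), or NULL for a "total"-only series.
#' @param seed integer seed (temperature, covariates and counts all derive
#'   from it deterministically).
#' @param overdispersion variance multiplier; 1 = Poisson, > 1 simulates
#'   overdispersed counts via a gamma frailty.
#' @param strata_risk optional named list of [risk_surface()] overriding
#'   `risk` for specific strata.
#' @return object of class `city_series`: list with `city_id`, `dates`,
#'   `deaths` (named list of integer vectors, always including `total`),
#'   `temp_mean`, `rh`, `pm25`, `o3`.
#' @export
simulate_city <- function(climate, risk, baseline, strata_weights = NULL,
                          seed = 1L, overdispersion = 1,
                          strata_risk = NULL) {
  stopifnot(inherits(climate, "city_climate_spec"),
            inherits(risk, "risk_surface"),
            inherits(baseline, "baseline_spec"))
  L <- risk$max_lag
  dates_full <- climate_dates(climate, burn_in = L)
  dates <- climate_dates(climate, burn_in = 0L)
  if (length(dates) <= L)
    stopf("series shorter than the lag history (%d days)", L)
  if (!is.null(strata_weights)) {
    if (is.null(names(strata_weights)) || any(!nzchar(names(strata_weights))))
      stopf("`strata_weights` must be named")
    if (abs(sum(strata_weights) - 1) > 1e-8)
      stopf("`strata_weights` must sum to 1")
  }
  if (!is.null(strata_risk) && is.null(strata_weights))
    stopf("`strata_risk` requires `strata_weights`")

  temp_full <- simulate_temperature(climate, child_seed(seed, "temp"),
                                    burn_in = L)
  temp <- temp_full[(L + 1L):length(temp_full)]
  n <- length(dates)

  covars <- with_seed(child_seed(seed, "covariates"), {
    rh <- pmin(pmax(stats::rnorm(n, climate$rh_mean, climate$rh_sd), 0), 100)
    lmu <- function(m, s) log(m^2 / sqrt(m^2 + s^2))
    lsd <- function(m, s) sqrt(log(1 + s^2 / m^2))
    pm25 <- stats::rlnorm(n, lmu(climate$pm25_mean, climate$pm25_sd),
                          lsd(climate$pm25_mean, climate$pm25_sd))
    o3 <- stats::rlnorm(n, lmu(climate$o3_mean, climate$o3_sd),
                        lsd(climate$o3_mean, climate$o3_sd))
    list(rh = rh, pm25 = pm25, o3 = o3)
  })

  base_lr <- baseline_log_rate(baseline, dates)

  deaths <- with_seed(child_seed(seed, "deaths"), {
    frailty <- if (overdispersion > 1) {
      # gamma frailty with var = (overdispersion - 1) / mu approximately:
      # shape chosen so Var(Y) ~ overdispersion * E(Y) at the baseline mean
      shp <- baseline$mean_daily_deaths / (overdispersion - 1)
      stats::rgamma(n, shape = shp, rate = shp)
    } else rep(1, n)
    if (is.null(strata_risk)) {
      contrib <- lagged_risk_contribution(temp_full, risk)
      lambda <- exp(base_lr + contrib) * frailty
      total <- stats::rpois(n, lambda)
      out <- list(total = total)
      if (!is.null(strata_weights)) {
        counts <- vapply(seq_len(n), function(t)
          drop(stats::rmultinom(1, total[t], strata_weights)),
          numeric(length(strata_weights)))
        counts <- matrix(counts, nrow = length(strata_weights))
        for (s in seq_along(strata_weights))
          out[[names(strata_weights)[s]]] <- as.integer(counts[s, ])
      }
      out
    } else {
      out <- list()
      total <- integer(n)
      for (s in names(strata_weights)) {
        rs <- if (!is.null(strata_risk[[s]])) strata_risk[[s]] else risk
        if (rs$max_lag != L) stopf("stratum surface max_lag mismatch")
        contrib <- lagged_risk_contribution(temp_full, rs)
        lambda <- strata_weights[[s]] * exp(base_lr + contrib) * frailty
        out[[s]] <- stats::rpois(n, lambda)
        total <- total + out[[s]]
      }
      c(list(total = total), out)
    }
  })

  structure(list(city_id = climate$city_id, dates = dates,
                 deaths = lapply(deaths, as.integer),
                 temp_mean = temp, rh = covars$rh, pm25 = covars$pm25,
                 o3 = covars$o3),
            class = "city_series")
}

#' @export
print.city_series <- function(x, ...) {
  cat(sprintf("<city_series> %s: %d days (%s to %s), strata: %s\n",
              x$city_id, length(x$dates), min(x$dates), max(x$dates),
              paste(names(x$deaths), collapse = ", ")))
  invisible(x)
}

#' Simulate a multi-city panel
#'
#' @param climates list of [city_climate_spec()].
#' @param risk shared [risk_surface()].
#' @param baselines a single [baseline_mortality_spec()] or a list, one per
#'   city.
#' @param strata_weights as in [simulate_city()].
#' @param seed master seed; per-city seeds are derived with [child_seed()].
#' @param ... passed to [simulate_city()].
#' @return named list of `city_series`.
#' @export
simulate_panel <- function(climates, risk, baselines, strata_weights = NULL,
                           seed = 1L, ...) {
  if (inherits(baselines, "baseline_spec"))
    baselines <- rep(list(baselines), length(climates))
  stopifnot(length(baselines) == length(climates))
  out <- lapply(seq_along(climates), function(i)
    simulate_city(climates[[i]], risk, baselines[[i]], strata_weights,
                  seed = child_seed(seed, "city", i), ...))
  names(out) <- vapply(climates, `[[`, "", "city_id")
  out
}

panel_to_dt <- function(panel) {
  data.table::rbindlist(lapply(panel, function(s) {
    data.table::rbindlist(lapply(names(s$deaths), function(st)
      data.table::data.table(city = s$city_id,
                             date = format(s$dates, "%Y-%m-%d"),
                             stratum = st, deaths = s$deaths[[st]],
                             temp_mean = s$temp_mean, rh = s$rh,
                             pm25 = s$pm25, o3 = s$o3)))
  }))
}

#' Write a panel of city series to CSV
#'
#' Long format, one row per city x date x stratum, columns
#' `city,date,stratum,deaths,temp_mean,rh,pm25,o3`. An optional JSON sidecar
#' (`<path>.truth.json`) records ground-truth settings for recovery tests.
#'
#' @param panel list of `city_series` (as from [simulate_panel()]).
#' @param path output CSV path.
#' @param truth optional list serialized alongside as JSON.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, truth = NULL) {
  if (inherits(panel, "city_series")) panel <- list(panel)
  dt <- panel_to_dt(panel)
  data.table::fwrite(dt, path)
  if (!is.null(truth))
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a panel of city series from CSV
#'
#' Validates the schema: required columns, strictly consecutive dates per
#' city, non-negative integer deaths, and stratum counts summing to the
#' total wherever strata beyond "total" are present.
#'
#' @param path CSV path as written by [write_panel()].
#' @return named list of `city_series`.
#' @export
read_panel <- function(path) {
  need <- c("city", "date", "stratum", "deaths", "temp_mean", "rh", "pm25",
            "o3")
  dt <- data.table::fread(path, colClasses = list(character = c("city", "date", "stratum")))
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stopf("panel file is missing column(s): %s", paste(miss, collapse = ", "))
  if (!is_count(dt$deaths)) {
    bad <- which(!(dt$deaths >= 0 & abs(dt$deaths - round(dt$deaths)) < 1e-8))
    stopf("`deaths` must be non-negative integers (offending rows: %s)",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  out <- list()
  for (ct in unique(dt$city)) {
    sub <- dt[dt$city == ct, ]
    strata <- unique(sub$stratum)
    if (!"total" %in% strata)
      stopf("city %s has no 'total' stratum", ct)
    tot <- sub[sub$stratum == "total", ]
    dts <- as.Date(tot$date)
    o <- order(dts); tot <- tot[o, ]; dts <- dts[o]
    gaps <- which(diff(as.integer(dts)) != 1L)
    if (length(gaps))
      stopf("city %s has non-consecutive dates (gap between %s and %s)",
            ct, dts[gaps[1]], dts[gaps[1] + 1])
    deaths <- list(total = as.integer(tot$deaths))
    for (st in setdiff(strata, "total")) {
      ss <- sub[sub$stratum == st, ]
      ss <- ss[order(as.Date(ss$date)), ]
      if (nrow(ss) != nrow(tot))
        stopf("city %s stratum %s has %d rows, expected %d", ct, st,
              nrow(ss), nrow(tot))
      deaths[[st]] <- as.integer(ss$deaths)
    }
    if (length(deaths) > 1L) {
      ssum <- Reduce(`+`, deaths[setdiff(names(deaths), "total")])
      if (any(ssum != deaths$total))
        stopf("city %s: stratum deaths do not sum to total on %d day(s)",
              ct, sum(ssum != deaths$total))
    }
    out[[ct]] <- structure(list(city_id = ct, dates = dts, deaths = deaths,
                                temp_mean = tot$temp_mean, rh = tot$rh,
                                pm25 = tot$pm25, o3 = tot$o3),
                           class = "city_series")
  }
  out
}

#' Reference four-city synthetic panel
#'
#' The stated world for validation runs: four cities with climates patterned
#' on a basin gradient (cool north, warm south), a shared cold-dominant
#' U-shaped surface with true MMT 25 degrees C, and baseline death counts
#' spanning the range seen in multi-city registry studies.
#'
#' @param seed master seed.
#' @param n_years years per city.
#' @param strata_weights optional strata, as in [simulate_city()].
#' @param risk override the default [default_risk_surface()].
#' @param mean_deaths per-city mean daily deaths (length 4).
#' @return named list of `city_series` with attribute `"truth"`.
#' @export
reference_panel <- function(seed = 1L, n_years = 6L, strata_weights = NULL,
                            risk = default_risk_surface(),
                            mean_deaths = c(242, 58, 47, 18)) {
  climates <- list(
    city_climate_spec("city_a", n_years, annual_mean_temp = 16.8,
                      seasonal_amplitude = 7.5, daily_sd = 2.4),
    city_climate_spec("city_b", n_years, annual_mean_temp = 18.9,
                      seasonal_amplitude = 7.6, daily_sd = 2.4,
                      rh_mean = 78.6),
    city_climate_spec("city_c", n_years, annual_mean_temp = 16.3,
                      seasonal_amplitude = 7.8, daily_sd = 2.5,
                      rh_mean = 70.1, pm25_mean = 26.5, pm25_sd = 17),
    city_climate_spec("city_d", n_years, annual_mean_temp = 21.6,
                      seasonal_amplitude = 5.8, daily_sd = 2.0,
                      rh_mean = 54.2, pm25_mean = 29.4, pm25_sd = 12.7))
  baselines <- lapply(mean_deaths, function(m)
    baseline_mortality_spec(mean_daily_deaths = m))
  panel <- simulate_panel(climates, risk, baselines, strata_weights,
                          seed = seed)
  attr(panel, "truth") <- list(true_mmt = risk$true_mmt, seed = seed,
                               n_years = n_years)
  panel
}
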