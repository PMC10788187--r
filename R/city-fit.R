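#' First-stage model specification
#'
#' Defines the per-city quasi-likelihood log-linear model: a temperature
#' cross-basis with `max_lag` days, natural cubic splines for relative
#' humidity and (optionally) PM2.5 and O3, a seasonal/long-term time spline,
#' and day-of-week indicators.
#'
#' @param max_lag maximum lag in days; 21 and 25 are the supported study
#'   configurations, other values >= 1 are allowed.
#' @param exposure_percentiles temperature knot percentiles.
#' @param n_lag_knots interior knots on the (log) lag axis.
#' @param confounder_df natural cubic df for RH/PM2.5/O3.
#' @param time_df_per_year time-spline df per calendar year.
#' @param dow include day-of-week indicators?
#' @param family `"poisson"` or `"quasipoisson"` (same point estimates; the
#'   latter rescales the covariance by the Pearson dispersion).
#' @param include_pm25,include_o3 adjust for the pollutants?
#' @return object of class `model_spec`.
#' @export
model_spec <- function(max_lag = 25L, exposure_percentiles = c(25, 50, 75),
                       n_lag_knots = 3L, confounder_df = 4L,
                       time_df_per_year = 8L, dow = TRUE,
                       family = c("poisson", "quasipoisson"),
                       include_pm25 = TRUE, include_o3 = TRUE) {
  family <- match.arg(family)
  if (max_lag < 1) stopf("`max_lag` must be >= 1")
  if (confounder_df < 1 || time_df_per_year < 1)
    stopf("all degrees of freedom must be >= 1")
  structure(list(max_lag = as.integer(max_lag),
                 exposure_percentiles = exposure_percentiles,
                 n_lag_knots = as.integer(n_lag_knots),
                 confounder_df = as.integer(confounder_df),
                 time_df_per_year = as.integer(time_df_per_year),
                 dow = isTRUE(dow), family = family,
                 include_pm25 = isTRUE(include_pm25),
                 include_o3 = isTRUE(include_o3)),
            class = "model_spec")
}

#' Identify usable regression rows
#'
#' Rows with a missing outcome or missing covariates are excluded from the
#' likelihood, but their temperatures still populate the lag histories of
#' later rows; a missing temperature invalidates its own row and the
#' `max_lag` following rows (incomplete lag history). The first `max_lag`
#' rows are always excluded.
#'
#' @param series a `city_series`.
#' @param stratum outcome stratum label.
#' @param max_lag lag history length.
#' @return logical vector marking usable rows; attributes `n_candidate` and
#'   `n_missing` summarize the exclusions.
#' @export
drop_missing <- function(series, stratum = "total", max_lag = 25L) {
  y <- series$deaths[[stratum]]
  if (is.null(y)) stopf("stratum '%s' not present in series", stratum)
  n <- length(y)
  keep <- seq_len(n) > max_lag
  # incomplete lag history from missing temperatures
  na_t <- which(is.na(series$temp_mean))
  for (t in na_t) keep[t:min(n, t + max_lag)] <- FALSE
  cand <- sum(seq_len(n) > max_lag)
  keep <- keep & !is.na(y) & !is.na(series$rh) & !is.na(series$pm25) &
    !is.na(series$o3)
  n_missing <- cand - sum(keep)
  if (cand > 0 && n_missing / cand > 0.5)
    stopf("more than 50%% of candidate rows are unusable (%d of %d)",
          n_missing, cand)
  if (cand > 0 && n_missing / cand > 0.2)
    warnf("more than 20%% of candidate rows are unusable (%d of %d)",
          n_missing, cand)
  structure(keep, n_candidate = cand, n_missing = n_missing)
}

#' Fit the first-stage model for one city and stratum
#'
#' (Quasi-)Poisson IRLS regression of daily deaths on the temperature
#' cross-basis plus confounder, trend and day-of-week terms. Returns the
#' cross-basis coefficient block with its covariance, the reduced overall
#' cumulative curve, and the city's temperature percentile table.
#'
#' @param series a `city_series` (>= 2 years recommended).
#' @param stratum outcome stratum label (default `"total"`).
#' @param spec a [model_spec()].
#' @return object of class `city_fit` with elements `city_id`, `stratum`,
#'   `full_coef`, `full_vcov`, `cb_spec`, `reduced` ([reduce_overall()]
#'   result), `dispersion`, `n_days_used`, `converged`, `temp_percentiles`.
#' @export
fit_city <- function(series, stratum = "total", spec = model_spec()) {
  stopifnot(inherits(series, "city_series"), inherits(spec, "model_spec"))
  y_all <- series$deaths[[stratum]]
  if (is.null(y_all)) stopf("stratum '%s' not present in series", stratum)
  L <- spec$max_lag
  if (length(series$dates) < 2 * 365)
    warnf("less than 2 years of data for %s/%s; estimates may be unstable",
          series$city_id, stratum)

  cb_spec <- default_crossbasis_spec(series$temp_mean, max_lag = L,
                                     exposure_percentiles = spec$exposure_percentiles,
                                     n_lag_knots = spec$n_lag_knots)
  cb <- build_crossbasis(series$temp_mean, cb_spec)

  keep <- drop_missing(series, stratum, max_lag = L)
  keep <- keep & attr(cb, "complete")

  blocks <- list(cb = cb)
  blocks$rh <- evaluate_basis(series$rh, ns_spec_by_df(series$rh, spec$confounder_df))
  colnames(blocks$rh) <- paste0("rh", seq_len(ncol(blocks$rh)))
  if (spec$include_pm25) {
    blocks$pm25 <- evaluate_basis(series$pm25,
                                  ns_spec_by_df(series$pm25, spec$confounder_df))
    colnames(blocks$pm25) <- paste0("pm25_", seq_len(ncol(blocks$pm25)))
  }
  if (spec$include_o3) {
    blocks$o3 <- evaluate_basis(series$o3,
                                ns_spec_by_df(series$o3, spec$confounder_df))
    colnames(blocks$o3) <- paste0("o3_", seq_len(ncol(blocks$o3)))
  }
  tb <- time_basis(series$dates, spec$time_df_per_year)
  colnames(tb) <- paste0("time", seq_len(ncol(tb)))
  blocks$time <- tb
  if (spec$dow) {
    dow <- factor(format(series$dates, "%u"), levels = as.character(1:7))
    Dm <- stats::model.matrix(~dow)[, -1, drop = FALSE]
    colnames(Dm) <- paste0("dow", 2:7)
    blocks$dow <- Dm
  }
  X <- cbind(`(Intercept)` = 1, do.call(cbind, blocks))
  cb_cols <- 1L + seq_len(ncol(cb))

  Xk <- X[keep, , drop = FALSE]
  yk <- y_all[keep]
  if (mean(yk) < 3)
    warnf("%s/%s: mean daily deaths %.2f < 3; first-stage curve will be noisy (BLUP shrinkage recommended)",
          series$city_id, stratum, mean(yk))

  qrX <- qr(Xk)
  if (qrX$rank < ncol(Xk)) {
    bad <- colnames(Xk)[qrX$pivot[(qrX$rank + 1):ncol(Xk)]]
    stopf("design matrix is rank deficient; collinear columns: %s",
          paste(bad, collapse = ", "))
  }

  fit <- stats::glm.fit(Xk, yk, family = stats::poisson(),
                        control = list(epsilon = 1e-9, maxit = 100))
  if (!fit$converged)
    stopf("IRLS did not converge in 100 iterations for %s/%s (deviance %.4g)",
          series$city_id, stratum, fit$deviance)

  w <- fit$weights
  XtWX <- crossprod(Xk * sqrt(w))
  V <- chol2inv(chol(XtWX))
  mu <- fit$fitted.values
  pearson <- sum((yk - mu)^2 / mu) / fit$df.residual
  dispersion <- if (spec$family == "quasipoisson") pearson else 1
  V <- V * dispersion

  full_coef <- fit$coefficients[cb_cols]
  full_vcov <- V[cb_cols, cb_cols, drop = FALSE]
  ptab <- temp_percentile_table(series$temp_mean)
  reduced <- reduce_overall(full_coef, full_vcov, cb_spec,
                            temp_percentiles = ptab)
  structure(list(city_id = series$city_id, stratum = stratum,
                 full_coef = full_coef, full_vcov = full_vcov,
                 cb_spec = cb_spec, reduced = reduced,
                 coefficients = fit$coefficients, vcov_all = V,
                 dispersion = pearson, family = spec$family,
                 n_days_used = length(yk), converged = fit$converged,
                 deviance = fit$deviance, temp_percentiles = ptab,
                 spec = spec),
            class = "city_fit")
}

#' @export
print.city_fit <- function(x, ...) {
  cat(sprintf("<city_fit> %s/%s: %d days, %s, dispersion %.3f, cb df %d\n",
              x$city_id, x$stratum, x$n_days_used, x$family, x$dispersion,
              length(x$full_coef)))
  invisible(x)
}

#' Wald test of the cross-basis coefficient block
#'
#' @param fit a [fit_city()] result.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
wald_crossbasis <- function(fit) {
  th <- fit$full_coef
  stat <- drop(t(th) %*% solve(fit$full_vcov, th))
  df <- length(th)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
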