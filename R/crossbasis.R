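#' Cross-basis specification for a distributed lag non-linear model
#'
#' Combines an exposure basis (vx functions of temperature) with a lag basis
#' (vl functions of lag, evaluated at integer lags 0..L) into the
#' bi-dimensional basis of a DLNM. Columns are ordered exposure-major: all vl
#' lag columns of exposure function 1, then exposure function 2, and so on.
#'
#' @param exposure_spec [basis_spec()] for the exposure dimension.
#' @param lag_spec [basis_spec()] for the lag dimension; its boundary knots
#'   must be `c(0, max_lag)`.
#' @param max_lag maximum lag L in days (>= 1; 0 allowed for a degenerate
#'   unlagged basis).
#' @return An object of class `crossbasis_spec`.
#' @export
crossbasis_spec <- function(exposure_spec, lag_spec, max_lag) {
  stopifnot(inherits(exposure_spec, "basis_spec"),
            inherits(lag_spec, "basis_spec"))
  if (max_lag < 0) stopf("`max_lag` must be >= 0")
  if (max_lag > 0 && lag_spec$kind != "intercept" &&
      !isTRUE(all.equal(lag_spec$boundary_knots, c(0, max_lag))))
    stopf("lag basis boundary knots must span [0, max_lag]")
  if (max_lag == 0 && lag_spec$kind != "intercept")
    stopf("with max_lag = 0 the lag basis must be the intercept basis")
  structure(list(exposure_spec = exposure_spec, lag_spec = lag_spec,
                 max_lag = as.integer(max_lag)),
            class = "crossbasis_spec")
}

#' Default cross-basis specification used in the mortality model
#'
#' Quadratic B-spline in temperature with interior knots at the 25th, 50th
#' and 75th percentiles of the city's temperature distribution and boundary
#' knots at its min/max; natural cubic spline with intercept in the lag
#' dimension with interior knots equally spaced on the log-lag scale.
#'
#' @param temp observed temperature series for the city.
#' @param max_lag maximum lag in days (default 25).
#' @param exposure_percentiles percentiles for the temperature knots.
#' @param n_lag_knots interior knots on the lag axis.
#' @return a [crossbasis_spec()].
#' @export
default_crossbasis_spec <- function(temp, max_lag = 25L,
                                    exposure_percentiles = c(25, 50, 75),
                                    n_lag_knots = 3L) {
  exposure <- basis_spec("bspline_quadratic",
                         interior_knots = quantile_knots(temp, exposure_percentiles),
                         boundary_knots = range(temp, na.rm = TRUE),
                         intercept = FALSE)
  lag <- basis_spec("natural_cubic",
                    interior_knots = log_lag_knots(max_lag, n_lag_knots),
                    boundary_knots = c(0, max_lag),
                    intercept = TRUE)
  crossbasis_spec(exposure, lag, max_lag)
}

# Lag basis evaluated at integer lags 0..L: (L+1) x vl
lag_basis_matrix <- function(spec) {
  evaluate_basis(0:spec$max_lag, spec$lag_spec)
}

#' Build the cross-basis design matrix
#'
#' Row t, column (j, k) equals `sum_l R_j(x[t-l]) * C_k(l)` over lags
#' `l = 0..L`, with R the exposure basis and C the lag basis at integer lags.
#' The first L rows lack a complete lag history and are returned as NA rows;
#' they must be excluded from regression (attribute `"complete"` flags usable
#' rows). Missing exposures propagate NA into the L + 1 rows they touch.
#'
#' @param x temperature series (length > L).
#' @param spec a [crossbasis_spec()].
#' @return n x (vx*vl) matrix with attributes `"spec"` and `"complete"`.
#' @export
build_crossbasis <- function(x, spec) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  n <- length(x); L <- spec$max_lag
  if (n <= L) stopf("series length (%d) must exceed max_lag (%d)", n, L)
  R <- evaluate_basis(x, spec$exposure_spec)
  C <- lag_basis_matrix(spec)
  vx <- ncol(R); vl <- ncol(C)
  jj <- rep(seq_len(vx), each = vl) # exposure index per output column
  kk <- rep(seq_len(vl), times = vx) # lag-basis index per output column
  cb <- matrix(0, n, vx * vl)
  for (l in 0:L) {
    Rl <- R[c(rep(NA_integer_, l), seq_len(n - l)), , drop = FALSE]
    cb <- cb + Rl[, jj, drop = FALSE] *
      matrix(C[l + 1L, kk], n, vx * vl, byrow = TRUE)
  }
  if (L > 0) cb[seq_len(L), ] <- NA_real_
  colnames(cb) <- paste0("v", jj, ".l", kk)
  attr(cb, "spec") <- spec
  attr(cb, "complete") <- seq_len(n) > L & !is.na(rowSums(cb))
  cb
}

#' Reduce full cross-basis coefficients to the overall cumulative curve
#'
#' The overall cumulative exposure-response sums lag-specific contributions
#' over all integer lags; on the coefficient scale this is the linear map
#' `M = I_vx (x) s'` with `s = colSums(C)` the lag basis summed over lags.
#'
#' @param full_coef length vx*vl coefficient vector (exposure-major order).
#' @param full_vcov (vx*vl) x (vx*vl) covariance matrix.
#' @param spec the [crossbasis_spec()] the coefficients were fitted under.
#' @param temp_percentiles optional percentile table (see
#'   [temp_percentile_table()]) carried along for MMT search.
#' @return An object of class `reduced_fit`: `coef` (length vx), `vcov`
#'   (vx x vx), `exposure_spec`, `temp_percentiles`.
#' @export
reduce_overall <- function(full_coef, full_vcov, spec,
                           temp_percentiles = NULL) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  C <- lag_basis_matrix(spec)
  vx <- basis_df(spec$exposure_spec); vl <- ncol(C)
  if (length(full_coef) != vx * vl)
    stopf("`full_coef` has length %d, expected vx*vl = %d",
          length(full_coef), vx * vl)
  if (!all(dim(full_vcov) == vx * vl))
    stopf("`full_vcov` dimensions do not match vx*vl = %d", vx * vl)
  s <- colSums(C)
  M <- kronecker(diag(vx), matrix(s, nrow = 1))
  coef <- drop(M %*% full_coef)
  vcov <- M %*% full_vcov %*% t(M)
  structure(list(coef = coef, vcov = (vcov + t(vcov)) / 2,
                 exposure_spec = spec$exposure_spec,
                 temp_percentiles = temp_percentiles),
            class = "reduced_fit")
}

#' Predict the centered overall cumulative exposure-response curve
#'
#' @param fit a [reduce_overall()] result (or any list with `coef`, `vcov`,
#'   `exposure_spec`), e.g. a pooled or BLUP curve.
#' @param grid temperatures at which to evaluate.
#' @param center reference temperature (RR = 1 there); must lie inside the
#'   exposure basis boundary knots.
#' @param level confidence level for the Wald bands.
#' @return data.frame of class `curve_prediction` with columns `temp`,
#'   `log_rr`, `se`, `rr`, `rr_low`, `rr_high`.
#' @export
predict_curve <- function(fit, grid, center, level = 0.95) {
  spec <- fit$exposure_spec
  bk <- spec$boundary_knots
  if (center < bk[1] || center > bk[2])
    stopf("`center` (%g) outside exposure basis boundary [%g, %g]",
          center, bk[1], bk[2])
  B <- evaluate_basis(grid, spec, extrapolate = TRUE)
  B0 <- evaluate_basis(center, spec)
  D <- sweep(B, 2, drop(B0))
  log_rr <- drop(D %*% fit$coef)
  se <- sqrt(pmax(rowSums((D %*% fit$vcov) * D), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(temp = grid, log_rr = log_rr, se = se,
                    rr = exp(log_rr),
                    rr_low = exp(log_rr - z * se),
                    rr_high = exp(log_rr + z * se))
  class(out) <- c("curve_prediction", "data.frame")
  out
}

#' Lag-response curve at a given temperature
#'
#' Relative risk at each integer lag for exposure `at_temp` versus `center`,
#' from the full coefficient surface: the lag-l log RR is
#' `(R(at_temp) - R(center)) %*% Theta %*% C(l)` with Theta the vx x vl
#' coefficient matrix.
#'
#' @inheritParams reduce_overall
#' @param at_temp exposure temperature of interest.
#' @param center reference temperature.
#' @param level confidence level.
#' @return data.frame with `lag`, `log_rr`, `se`, `rr`, `rr_low`, `rr_high`.
#' @export
predict_lag_curve <- function(full_coef, full_vcov, spec, at_temp, center,
                              level = 0.95) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  bk <- spec$exposure_spec$boundary_knots
  if (center < bk[1] || center > bk[2])
    stopf("`center` (%g) outside exposure basis boundary [%g, %g]",
          center, bk[1], bk[2])
  dR <- drop(evaluate_basis(at_temp, spec$exposure_spec, extrapolate = TRUE)) -
    drop(evaluate_basis(center, spec$exposure_spec))
  C <- lag_basis_matrix(spec)
  z <- stats::qnorm(1 - (1 - level) / 2)
  res <- lapply(0:spec$max_lag, function(l) {
    v <- kronecker(dR, C[l + 1L, ]) # exposure-major
    lr <- sum(v * full_coef)
    se <- sqrt(max(drop(t(v) %*% full_vcov %*% v), 0))
    c(lag = l, log_rr = lr, se = se)
  })
  res <- as.data.frame(do.call(rbind, res))
  res$rr <- exp(res$log_rr)
  res$rr_low <- exp(res$log_rr - z * res$se)
  res$rr_high <- exp(res$log_rr + z * res$se)
  res
}
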