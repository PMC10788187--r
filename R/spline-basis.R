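#' One-dimensional spline basis specification
#'
#' Defines the spline bases used throughout the model: a quadratic B-spline
#' for the exposure (temperature) dimension and natural cubic splines for the
#' lag dimension, the confounders (relative humidity, PM2.5, O3) and the
#' long-term time trend.
#'
#' Degrees of freedom follow the usual conventions:
#' * `bspline_quadratic`: `length(interior_knots) + 2 + intercept`
#' * `natural_cubic`: `length(interior_knots) + 1 + intercept`
#'
#' @param kind `"bspline_quadratic"`, `"natural_cubic"`, or `"intercept"`
#'   (a single constant column, used as the degenerate lag basis at L = 0).
#' @param interior_knots numeric vector of strictly increasing knots, all
#'   strictly inside the boundary knots.
#' @param boundary_knots length-2 numeric vector (lower, upper).
#' @param intercept logical; keep the basis column spanning the constant?
#' @return An object of class `basis_spec`.
#' @seealso [evaluate_basis()], [quantile_knots()], [log_lag_knots()]
#' @export
basis_spec <- function(kind = c("bspline_quadratic", "natural_cubic",
                                "intercept"),
                       interior_knots = numeric(),
                       boundary_knots,
                       intercept = FALSE) {
  kind <- match.arg(kind)
  if (kind == "intercept") {
    if (length(interior_knots))
      stopf("an intercept basis takes no interior knots")
    if (missing(boundary_knots)) boundary_knots <- c(0, 1)
    return(structure(list(kind = kind, interior_knots = numeric(),
                          boundary_knots = as.numeric(boundary_knots),
                          intercept = TRUE),
                     class = "basis_spec"))
  }
  interior_knots <- as.numeric(interior_knots)
  boundary_knots <- as.numeric(boundary_knots)
  if (length(boundary_knots) != 2L || !all(is.finite(boundary_knots)) ||
      boundary_knots[1] >= boundary_knots[2])
    stopf("`boundary_knots` must be two finite increasing values")
  if (length(interior_knots)) {
    if (any(!is.finite(interior_knots)))
      stopf("`interior_knots` must be finite")
    if (is.unsorted(interior_knots, strictly = TRUE))
      stopf("`interior_knots` must be strictly increasing")
    if (min(interior_knots) <= boundary_knots[1] ||
        max(interior_knots) >= boundary_knots[2])
      stopf("`interior_knots` must lie strictly inside `boundary_knots`")
  }
  structure(list(kind = kind, interior_knots = interior_knots,
                 boundary_knots = boundary_knots,
                 intercept = isTRUE(intercept)),
            class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf("<basis_spec> %s, %d interior knots, boundary [%g, %g], %s, df = %d\n",
              x$kind, length(x$interior_knots), x$boundary_knots[1],
              x$boundary_knots[2],
              if (x$intercept) "intercept" else "no intercept", basis_df(x)))
  invisible(x)
}

#' Degrees of freedom of a basis specification
#' @param spec a [basis_spec()].
#' @return integer column count of the realized basis.
#' @export
basis_df <- function(spec) {
  k <- length(spec$interior_knots)
  switch(spec$kind,
         bspline_quadratic = k + 2L + spec$intercept,
         natural_cubic     = k + 1L + spec$intercept,
         intercept         = 1L)
}

#' Knots at empirical percentiles of a variable
#'
#' Uses the type-7 quantile rule (linear interpolation between order
#' statistics) so knot placement is reproducible.
#'
#' @param x numeric vector of observations (NAs dropped).
#' @param percentiles percentiles in (0, 100); default the quartiles used for
#'   the temperature exposure basis.
#' @return sorted numeric knot positions.
#' @export
quantile_knots <- function(x, percentiles = c(25, 50, 75)) {
  x <- x[!is.na(x)]
  if (!length(x)) stopf("`x` has no non-missing values")
  if (any(percentiles <= 0 | percentiles >= 100))
    stopf("`percentiles` must be strictly inside (0, 100)")
  sort(unname(stats::quantile(x, probs = percentiles / 100, type = 7)))
}

#' Lag knots equally spaced on the log scale
#'
#' Places `n_knots` interior knots on the lag axis at values equally spaced
#' in log between lag 1 and `max_lag` (endpoints excluded), i.e.
#' `max_lag^(j / (n_knots + 1))` for `j = 1, ..., n_knots`.
#'
#' @param max_lag maximum lag in days (>= 1).
#' @param n_knots number of interior knots.
#' @return numeric knot positions on the lag axis.
#' @export
log_lag_knots <- function(max_lag, n_knots = 3L) {
  if (max_lag < 1) stopf("`max_lag` must be >= 1")
  if (n_knots < 1) stopf("`n_knots` must be >= 1")
  if (n_knots >= max_lag)
    stopf("`n_knots` (%d) must be smaller than `max_lag` (%d)",
          n_knots, max_lag)
  max_lag^(seq_len(n_knots) / (n_knots + 1))
}

# Full (intercept-included) quadratic B-spline design via the standard
# repeated-boundary knot vector; columns = interior + 3.
bspline_full <- function(x, spec, derivs = 0L) {
  ord <- 3L # quadratic
  kn <- c(rep(spec$boundary_knots[1], ord), spec$interior_knots,
          rep(spec$boundary_knots[2], ord))
  splines::splineDesign(kn, x = x, ord = ord,
                        derivs = rep(derivs, length(x)))
}

#' Evaluate a spline basis at given points
#'
#' B-spline bases are only defined inside their boundary knots: evaluation
#' outside is an error during fitting, but `extrapolate = TRUE` extends the
#' basis linearly beyond the boundaries (value plus first derivative at the
#' boundary), which is only appropriate for prediction grids. Natural cubic
#' bases are linear beyond their boundaries by construction and evaluate
#' everywhere.
#'
#' @param x numeric vector (NAs propagate to NA rows).
#' @param spec a [basis_spec()].
#' @param extrapolate allow linear extrapolation beyond boundary knots for
#'   B-spline bases.
#' @return numeric matrix `length(x)` x `basis_df(spec)` with the spec
#'   attached as attribute `"spec"`.
#' @export
evaluate_basis <- function(x, spec, extrapolate = FALSE) {
  stopifnot(inherits(spec, "basis_spec"))
  x <- as.numeric(x)
  ok <- !is.na(x)
  lo <- spec$boundary_knots[1]; hi <- spec$boundary_knots[2]
  out <- matrix(NA_real_, length(x), basis_df(spec))
  if (spec$kind == "intercept") {
    out[ok, 1L] <- 1
    colnames(out) <- "b1"
    attr(out, "spec") <- spec
    return(out)
  }
  if (spec$kind == "bspline_quadratic") {
    below <- ok & x < lo; above <- ok & x > hi
    if (any(below | above) && !extrapolate)
      stopf("%d value(s) outside boundary knots [%g, %g]; B-spline bases do not extrapolate during fitting",
            sum(below | above), lo, hi)
    xc <- pmin(pmax(x[ok], lo), hi)
    B <- bspline_full(xc, spec)
    if (any(below | above)) {
      d_lo <- bspline_full(lo, spec, derivs = 1L)
      d_hi <- bspline_full(hi, spec, derivs = 1L)
      idx <- which(below[ok]) # indices within the ok subset
      if (length(idx))
        B[idx, ] <- B[idx, , drop = FALSE] +
          (x[ok][idx] - lo) %o% drop(d_lo)
      idx <- which(above[ok])
      if (length(idx))
        B[idx, ] <- B[idx, , drop = FALSE] +
          (x[ok][idx] - hi) %o% drop(d_hi)
    }
    if (!spec$intercept) B <- B[, -1L, drop = FALSE]
    out[ok, ] <- B
  } else {
    out[ok, ] <- splines::ns(x[ok], knots = spec$interior_knots,
                             Boundary.knots = spec$boundary_knots,
                             intercept = spec$intercept)
  }
  colnames(out) <- paste0("b", seq_len(ncol(out)))
  attr(out, "spec") <- spec
  out
}

#' Natural cubic time basis for seasonal and long-term trend control
#'
#' Builds a natural cubic spline on the day index with
#' `round(df_per_year * n_years)` total degrees of freedom (year fraction
#' computed from the actual calendar span), interior knots at equally spaced
#' quantiles of the index. No intercept column (the model supplies one).
#'
#' @param dates a `Date` vector of strictly consecutive calendar days.
#' @param df_per_year integer degrees of freedom per year (>= 1).
#' @return basis matrix as from [evaluate_basis()].
#' @export
time_basis <- function(dates, df_per_year) {
  dates <- as.Date(dates)
  if (length(dates) < 2L) stopf("need at least two dates")
  if (any(diff(as.integer(dates)) != 1L))
    stopf("`dates` must be strictly consecutive calendar days")
  if (df_per_year < 1) stopf("`df_per_year` must be >= 1")
  n <- length(dates)
  years <- n / 365.25
  df <- max(2L, as.integer(round(df_per_year * years)))
  idx <- seq_len(n)
  # natural cubic without intercept: df = interior + 1
  n_int <- df - 1L
  probs <- seq_len(n_int) / (n_int + 1L)
  interior <- unname(stats::quantile(idx, probs, type = 7))
  spec <- basis_spec("natural_cubic", interior_knots = interior,
                     boundary_knots = c(1, n), intercept = FALSE)
  evaluate_basis(idx, spec)
}

# Natural cubic spline spec with `df` total columns (no intercept), interior
# knots at equally spaced quantiles of x -- the ns(x, df) convention used for
# the confounder terms.
ns_spec_by_df <- function(x, df) {
  x <- x[!is.na(x)]
  if (df < 1) stopf("confounder df must be >= 1")
  n_int <- df - 1L
  interior <- if (n_int > 0)
    unname(stats::quantile(x, seq_len(n_int) / (n_int + 1L), type = 7))
  else numeric()
  interior <- unique(interior)
  basis_spec("natural_cubic", interior_knots = interior,
             boundary_knots = range(x), intercept = FALSE)
}
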