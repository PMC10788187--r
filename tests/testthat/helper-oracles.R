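# Independent oracles, deliberately written from textbook definitions and
# kept free of the package's own basis/attribution code paths.

# --- Cox-de Boor recursion for B-splines -----------------------------------
# Full basis over knot vector kn (boundary knots repeated ord times),
# matching the canonical B-spline basis elementwise.
oracle_bspline <- function(x, interior, boundary, degree = 2) {
  ord <- degree + 1
  kn <- c(rep(boundary[1], ord), interior, rep(boundary[2], ord))
  nb <- length(kn) - ord
  B <- matrix(0, length(x), nb + degree) # order-1 bases first, trimmed later
  # order 1 (piecewise constant); right-closed at the last boundary
  K <- length(kn)
  B0 <- matrix(0, length(x), K - 1)
  for (j in seq_len(K - 1)) {
    if (kn[j] < kn[j + 1])
      B0[, j] <- as.numeric(x >= kn[j] & (x < kn[j + 1] |
                  (x == boundary[2] & kn[j + 1] == boundary[2])))
  }
  Bm <- B0
  for (d in seq_len(degree)) {
    nb_d <- ncol(Bm) - 1
    Bn <- matrix(0, length(x), nb_d)
    for (j in seq_len(nb_d)) {
      a <- 0
      if (kn[j + d] > kn[j])
        a <- (x - kn[j]) / (kn[j + d] - kn[j]) * Bm[, j]
      b <- 0
      if (kn[j + d + 1] > kn[j + 1])
        b <- (kn[j + d + 1] - x) / (kn[j + d + 1] - kn[j + 1]) * Bm[, j + 1]
      Bn[, j] <- a + b
    }
    Bm <- Bn
  }
  Bm
}

# --- natural cubic spline via truncated powers then constraints ------------
# ESL-style basis: with knots xi_1 < ... < xi_K (interior plus the two
# boundary knots), N1 = 1, N2 = x, N_{k+2} = d_k - d_{K-1} where
# d_k = ((x - xi_k)_+^3 - (x - xi_K)_+^3) / (xi_K - xi_k).
# Linear beyond the boundary knots by construction.
oracle_natural_cubic <- function(x, interior, boundary) {
  xi <- sort(c(boundary, interior))
  K <- length(xi)
  tp <- function(v) pmax(v, 0)^3
  d <- function(k) (tp(x - xi[k]) - tp(x - xi[K])) / (xi[K] - xi[k])
  cols <- list(rep(1, length(x)), x)
  for (k in seq_len(K - 2)) cols[[k + 2]] <- d(k) - d(K - 1)
  do.call(cbind, cols)
}

# max residual of projecting each column of A onto the column span of B
span_residual <- function(A, B) {
  fit <- qr(B)
  max(abs(A - qr.fitted(fit, A)))
}

# --- brute-force DLNM surface evaluation -----------------------------------
# Direct evaluation of sum_l f(x_{t-l}, l) for a coefficient surface theta
# (exposure-major vx x vl blocks), looping day by day and lag by lag.
oracle_surface_sum <- function(x, theta, exposure_spec, lag_spec, L) {
  n <- length(x)
  R <- evaluate_basis(x, exposure_spec)
  C <- evaluate_basis(0:L, lag_spec)
  vx <- ncol(R); vl <- ncol(C)
  Theta <- matrix(theta, vx, vl, byrow = TRUE) # exposure-major vector
  out <- rep(NA_real_, n)
  for (t in (L + 1):n) {
    acc <- 0
    for (l in 0:L)
      acc <- acc + drop(R[t - l, ] %*% Theta %*% C[l + 1, ])
    out[t] <- acc
  }
  out
}

# --- univariate REML oracle ------------------------------------------------
# Scalar random-effects meta-analysis: profile restricted likelihood in the
# single variance component psi, optimized on a dense grid + refinement.
oracle_uni_reml <- function(theta, s2) {
  nll <- function(psi) {
    v <- psi + s2
    w <- 1 / v
    mu <- sum(w * theta) / sum(w)
    0.5 * (sum(log(v)) + log(sum(w)) + sum(w * (theta - mu)^2))
  }
  opt <- stats::optimize(nll, c(0, max(stats::var(theta) * 10, 1e-6)),
                         tol = 1e-12)
  psi <- opt$minimum
  w <- 1 / (psi + s2)
  mu <- sum(w * theta) / sum(w)
  list(psi = psi, mu = mu, se_mu = sqrt(1 / sum(w)))
}

# --- day-by-day attribution loop -------------------------------------------
oracle_attribution_loop <- function(coef, exposure_spec, temps, deaths, mmt,
                                    max_lag = 0) {
  b0 <- drop(evaluate_basis(mmt, exposure_spec))
  an <- numeric(0)
  for (t in seq_along(temps)) {
    if (t <= max_lag) next
    bt <- drop(evaluate_basis(temps[t], exposure_spec, extrapolate = TRUE))
    lr <- sum((bt - b0) * coef)
    an <- c(an, deaths[t] * (1 - exp(-lr)))
  }
  an
}
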