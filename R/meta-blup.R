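#' Multivariate random-effects meta-analysis of reduced city curves
#'
#' Pools per-city overall-cumulative coefficient vectors under the model
#' `theta_i ~ N(mu, Psi + S_i)`, with `S_i` the within-city covariance and
#' `Psi` the between-city covariance. `Psi` is estimated by REML (profiled
#' restricted likelihood, Cholesky-parameterized so it stays positive
#' semi-definite) or by a method-of-moments estimator; REML falls back to
#' moments with a warning if the optimizer fails. Comparability across
#' cities relies on percentile-anchored exposure knots: the curve is pooled
#' on the coefficient scale.
#'
#' @param fits list of [reduce_overall()] results (class `reduced_fit`), or
#'   of [fit_city()] results (their `$reduced` is used). A single fit is a
#'   degenerate pass-through with `Psi = 0`.
#' @param method `"reml"` (default) or `"mm"`.
#' @return object of class `pooled_model`: `fixed`, `fixed_vcov`, `psi`,
#'   `method`, `heterogeneity` (Q, df, I2), `city_ids`, plus the inputs
#'   needed by [blup()].
#' @export
pool_cities <- function(fits, method = c("reml", "mm")) {
  method <- match.arg(method)
  fits <- lapply(fits, function(f) if (inherits(f, "city_fit")) f$reduced else f)
  stopifnot(all(vapply(fits, inherits, TRUE, "reduced_fit")))
  k <- length(fits)
  if (k < 1) stopf("need at least one city")
  p <- length(fits[[1]]$coef)
  theta <- do.call(rbind, lapply(fits, `[[`, "coef")) # k x p, also for p = 1
  S <- lapply(fits, function(f) matrix(f$vcov, p, p))
  for (i in seq_len(k)) {
    if (length(fits[[i]]$coef) != p)
      stopf("city %d has %d coefficients, expected %d", i,
            length(fits[[i]]$coef), p)
    if (inherits(try(chol(S[[i]] + diag(1e-12, p)), silent = TRUE), "try-error"))
      stopf("within-city covariance of city %d is singular", i)
  }

  if (k == 1) {
    psi <- matrix(0, p, p)
    return(structure(list(fixed = drop(theta[1, ]), fixed_vcov = S[[1]],
                          psi = psi, method = method,
                          heterogeneity = NULL, theta = theta, S = S,
                          converged = TRUE, city_ids = names(fits)),
                     class = "pooled_model"))
  }

  fixed_given_psi <- function(psi) {
    U <- matrix(0, p, p); b <- numeric(p)
    W <- vector("list", k)
    for (i in seq_len(k)) {
      W[[i]] <- solve(psi + S[[i]])
      U <- U + W[[i]]
      b <- b + W[[i]] %*% theta[i, ]
    }
    Uinv <- solve(U)
    list(mu = drop(Uinv %*% b), vcov = Uinv, W = W, U = U)
  }

  # method-of-moments start/fallback: sample covariance of theta minus the
  # average within-city covariance, eigenvalue-clipped to PSD
  mm_psi <- function() {
    Sbar <- Reduce(`+`, S) / k
    Tcov <- stats::cov(theta)
    ee <- eigen((Tcov + t(Tcov)) / 2 - Sbar, symmetric = TRUE)
    lam <- pmax(ee$values, 0)
    ee$vectors %*% (t(ee$vectors) * lam)
  }

  reml_nll <- function(lpar) {
    Lm <- matrix(0, p, p)
    Lm[lower.tri(Lm, diag = TRUE)] <- lpar
    psi <- Lm %*% t(Lm)
    val <- 0; U <- matrix(0, p, p); b <- numeric(p)
    Ws <- vector("list", k)
    for (i in seq_len(k)) {
      ch <- tryCatch(chol(psi + S[[i]]), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      val <- val + 2 * sum(log(diag(ch)))
      Wi <- chol2inv(ch)
      Ws[[i]] <- Wi
      U <- U + Wi
      b <- b + Wi %*% theta[i, ]
    }
    chU <- tryCatch(chol(U), error = function(e) NULL)
    if (is.null(chU)) return(1e10)
    val <- val + 2 * sum(log(diag(chU)))
    mu <- drop(chol2inv(chU) %*% b)
    for (i in seq_len(k)) {
      r <- theta[i, ] - mu
      val <- val + drop(t(r) %*% Ws[[i]] %*% r)
    }
    0.5 * val
  }

  # analytic gradient of the restricted NLL w.r.t. the Cholesky factor:
  # G = 0.5 (sum W_i - sum W_i U^{-1} W_i - sum W_i r_i r_i' W_i),
  # d(nll)/dL = (G + G') L; the profiled mean drops out by the envelope
  # theorem (it minimizes the quadratic form at fixed weights)
  reml_grad <- function(lpar) {
    Lm <- matrix(0, p, p)
    Lm[lower.tri(Lm, diag = TRUE)] <- lpar
    psi <- Lm %*% t(Lm)
    Ws <- vector("list", k); U <- matrix(0, p, p); b <- numeric(p)
    for (i in seq_len(k)) {
      ch <- tryCatch(chol(psi + S[[i]]), error = function(e) NULL)
      if (is.null(ch)) return(rep(0, length(lpar)))
      Ws[[i]] <- chol2inv(ch)
      U <- U + Ws[[i]]
      b <- b + Ws[[i]] %*% theta[i, ]
    }
    Uinv <- solve(U)
    mu <- drop(Uinv %*% b)
    G <- matrix(0, p, p)
    for (i in seq_len(k)) {
      r <- theta[i, ] - mu
      Wr <- Ws[[i]] %*% r
      G <- G + Ws[[i]] - Ws[[i]] %*% Uinv %*% Ws[[i]] - Wr %*% t(Wr)
    }
    dL <- G %*% Lm # (G + G')L / 2 with G symmetric
    dL[lower.tri(dL, diag = TRUE)]
  }

  psi_mm <- mm_psi()
  converged <- TRUE
  if (method == "reml") {
    # Cholesky start from the (ridged) moment estimate
    Ls <- t(chol(psi_mm + diag(1e-6 * mean(diag(Reduce(`+`, S) / k)), p)))
    start <- Ls[lower.tri(Ls, diag = TRUE)]
    opt <- tryCatch(
      stats::optim(start, reml_nll, gr = reml_grad, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(opt) || opt$convergence != 0 || !is.finite(opt$value)) {
      warnf("REML did not converge; falling back to method of moments")
      psi <- psi_mm
      method <- "mm"
      converged <- FALSE
    } else {
      Lm <- matrix(0, p, p)
      Lm[lower.tri(Lm, diag = TRUE)] <- opt$par
      psi <- Lm %*% t(Lm)
    }
  } else {
    psi <- psi_mm
  }
  psi <- (psi + t(psi)) / 2

  fx <- fixed_given_psi(psi)
  het <- heterogeneity_stats(theta, S)
  structure(list(fixed = fx$mu, fixed_vcov = fx$vcov, psi = psi,
                 method = method, heterogeneity = het, theta = theta, S = S,
                 converged = converged,
                 nll = if (method == "reml" && converged) reml_nll else NULL,
                 city_ids = names(fits),
                 exposure_spec = fits[[1]]$exposure_spec),
            class = "pooled_model")
}

#' @export
print.pooled_model <- function(x, ...) {
  cat(sprintf("<pooled_model> %d cities, %d coefficients, method %s\n",
              nrow(x$theta), length(x$fixed), x$method))
  if (!is.null(x$heterogeneity))
    cat(sprintf("  Q = %.2f on %d df, I2 = %.1f%%\n",
                x$heterogeneity$Q, x$heterogeneity$df, x$heterogeneity$I2))
  invisible(x)
}

heterogeneity_stats <- function(theta, S) {
  k <- nrow(theta); p <- ncol(theta)
  if (k < 2) return(NULL)
  # fixed-effects (Psi = 0) pooled mean
  U <- matrix(0, p, p); b <- numeric(p)
  W <- lapply(S, solve)
  for (i in seq_len(k)) {
    U <- U + W[[i]]
    b <- b + W[[i]] %*% theta[i, ]
  }
  mu <- drop(solve(U, b))
  Q <- 0
  for (i in seq_len(k)) {
    r <- theta[i, ] - mu
    Q <- Q + drop(t(r) %*% W[[i]] %*% r)
  }
  df <- (k - 1) * p
  list(Q = Q, df = df, I2 = max(0, (Q - df) / Q) * 100,
       p_value = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Cochran Q and I-squared for a set of reduced fits
#'
#' Multivariate heterogeneity statistic against the fixed-effects pooled
#' mean: `Q = sum (theta_i - mu)' S_i^{-1} (theta_i - mu)`, referred to a
#' chi-squared with `(k - 1) * p` degrees of freedom.
#'
#' @param fits list of `reduced_fit` (or `city_fit`).
#' @return list with `Q`, `df`, `I2`, `p_value`, or `NULL` with fewer than
#'   two cities.
#' @export
heterogeneity <- function(fits) {
  fits <- lapply(fits, function(f) if (inherits(f, "city_fit")) f$reduced else f)
  if (length(fits) < 2) return(NULL)
  p <- length(fits[[1]]$coef)
  theta <- do.call(rbind, lapply(fits, `[[`, "coef"))
  heterogeneity_stats(theta, lapply(fits, function(f) matrix(f$vcov, p, p)))
}

#' Best linear unbiased predictions of city-specific curves
#'
#' Shrinks each city's estimate toward the pooled mean:
#' `blup_i = mu + Psi (Psi + S_i)^{-1} (theta_i - mu)`. The reported
#' covariance is the conditional variance `Psi - Psi (Psi + S_i)^{-1} Psi`
#' plus the propagated uncertainty of the fixed effects,
#' `(I - B_i) V(mu) (I - B_i)'` with `B_i = Psi (Psi + S_i)^{-1}`, so that a
#' city with `Psi = 0` inherits the pooled curve and its uncertainty.
#'
#' @param pooled a [pool_cities()] result.
#' @param fits the same list of fits used for pooling.
#' @return object of class `blup_set`: named list, one element per city with
#'   `coef`, `vcov`, `exposure_spec`, `temp_percentiles`.
#' @export
blup <- function(pooled, fits) {
  stopifnot(inherits(pooled, "pooled_model"))
  fits <- lapply(fits, function(f) if (inherits(f, "city_fit")) f$reduced else f)
  p <- length(pooled$fixed)
  if (length(fits[[1]]$coef) != p) stopf("dimension mismatch with pooled model")
  out <- lapply(seq_along(fits), function(i) {
    Si <- fits[[i]]$vcov
    B <- pooled$psi %*% solve(pooled$psi + Si)
    coef <- drop(pooled$fixed + B %*% (fits[[i]]$coef - pooled$fixed))
    IB <- diag(p) - B
    V <- pooled$psi - B %*% pooled$psi + IB %*% pooled$fixed_vcov %*% t(IB)
    list(coef = coef, vcov = (V + t(V)) / 2,
         exposure_spec = fits[[i]]$exposure_spec,
         temp_percentiles = fits[[i]]$temp_percentiles)
  })
  names(out) <- if (!is.null(names(fits))) names(fits) else pooled$city_ids
  structure(out, class = "blup_set")
}
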