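# simulate reduced fits directly at the coefficient level: theta_i ~
# N(mu, Psi + S_i) with known components; fast and exact for meta tests
sim_reduced <- function(k, p, mu, Psi, S_scale = 0.02, seed = 1) {
  withr::local_seed(seed)
  lapply(seq_len(k), function(i) {
    A <- matrix(rnorm(p * p, sd = S_scale), p)
    S <- crossprod(A) + diag(S_scale^2, p)
    eS <- eigen(Psi + S, symmetric = TRUE)
    half <- eS$vectors %*% (t(eS$vectors) * sqrt(pmax(eS$values, 0)))
    th <- drop(mu + half %*% rnorm(p))
    structure(list(coef = th, vcov = S,
                   exposure_spec = toy_exposure_spec()),
              class = "reduced_fit")
  })
}

test_that("single-city pooling is a degenerate pass-through", {
  f <- sim_reduced(1, 4, rep(0, 4), diag(0, 4))
  pm <- pool_cities(f)
  expect_equal(pm$fixed, f[[1]]$coef)
  expect_equal(pm$fixed_vcov, f[[1]]$vcov)
  expect_equal(pm$psi, matrix(0, 4, 4))
  expect_null(pm$heterogeneity)
})

test_that("pooled estimator is invariant to city ordering", {
  fits <- sim_reduced(6, 3, c(0.1, -0.2, 0.3), diag(0.05, 3), seed = 2)
  p1 <- pool_cities(fits, method = "reml")
  p2 <- pool_cities(rev(fits), method = "reml")
  expect_equal(p1$fixed, p2$fixed, tolerance = 1e-6)
  expect_equal(p1$psi, p2$psi, tolerance = 1e-5)
})

test_that("mm fallback equals inverse-variance weighting when Psi = 0 is forced", {
  fits <- sim_reduced(5, 3, rep(0, 3), diag(0, 3), seed = 3)
  # with Psi = 0 the weighted mean is the fixed-effects estimator
  W <- lapply(fits, function(f) solve(f$vcov))
  U <- Reduce(`+`, W)
  mu_fe <- drop(solve(U, Reduce(`+`, Map(function(w, f) w %*% f$coef, W, fits))))
  pm <- pool_cities(fits, method = "reml")
  # homogeneous simulation: Psi should be ~0, estimator ~ fixed-effects
  expect_lt(max(abs(pm$fixed - mu_fe)), 0.02)
})

test_that("vx = 1 REML matches the univariate oracle", {
  withr::local_seed(4)
  for (rep in 1:3) {
    k <- 10
    s2 <- runif(k, 0.01, 0.05)
    psi_true <- 0.03
    th <- rnorm(k, 0.5, sqrt(psi_true + s2))
    fits <- lapply(seq_len(k), function(i)
      structure(list(coef = th[i], vcov = matrix(s2[i], 1, 1)),
                class = "reduced_fit"))
    pm <- pool_cities(fits, method = "reml")
    or <- oracle_uni_reml(th, s2)
    expect_equal(drop(pm$psi), or$psi, tolerance = 1e-5)
    expect_equal(pm$fixed, or$mu, tolerance = 1e-6)
    expect_equal(sqrt(drop(pm$fixed_vcov)), or$se_mu, tolerance = 1e-6)
  }
})

test_that("REML gradient vanishes at the optimum", {
  fits <- sim_reduced(8, 3, c(0, 0.1, 0.2), diag(c(0.02, 0.01, 0.03)),
                      seed = 5)
  pm <- pool_cities(fits, method = "reml")
  expect_true(pm$converged)
  # numerical gradient of the restricted NLL at the Cholesky optimum
  Lm <- t(chol(pm$psi + diag(1e-10, 3)))
  par <- Lm[lower.tri(Lm, diag = TRUE)]
  g <- vapply(seq_along(par), function(j) {
    h <- 1e-5
    pp <- par; pp[j] <- pp[j] + h
    pmn <- par; pmn[j] <- pmn[j] - h
    (pm$nll(pp) - pm$nll(pmn)) / (2 * h)
  }, 0)
  expect_lt(max(abs(g)), 1e-3)
  expect_lte(pm$nll(par), pm$nll(par * 0) + 1e-8) # no worse than Psi = 0
})

test_that("blup shrinkage limits", {
  fits <- sim_reduced(4, 3, c(0.1, 0, -0.1), diag(0.02, 3), seed = 6)
  pm <- pool_cities(fits)
  # Psi = 0: every BLUP equals the pooled vector
  pm0 <- pm; pm0$psi <- matrix(0, 3, 3)
  b0 <- blup(pm0, fits)
  for (b in b0) expect_equal(b$coef, pm$fixed)
  # S_i -> 0: BLUP -> city estimate
  fits_big <- fits
  fits_big[[1]]$vcov <- fits[[1]]$vcov * 1e-6
  pm1 <- pm; pm1$psi <- diag(0.05, 3)
  b1 <- blup(pm1, fits_big)
  expect_equal(b1[[1]]$coef, fits_big[[1]]$coef, tolerance = 1e-4)
  # intermediate: shrinkage brings the BLUP closer to mu in the
  # (Psi + S_i)^{-1} norm than the raw estimate
  b2 <- blup(pm1, fits)
  for (i in seq_along(fits)) {
    M <- solve(pm1$psi + fits[[i]]$vcov)
    qn <- function(v) drop(t(v) %*% M %*% v)
    expect_lte(qn(b2[[i]]$coef - pm$fixed),
               qn(fits[[i]]$coef - pm$fixed) + 1e-12)
  }
  expect_error(blup(pm, fits[1:2][c(1, 2, 1)][1:1]), NA) # subset ok
})

test_that("heterogeneity: zero for identical cities, monotone in deviation", {
  base <- structure(list(coef = c(0.1, 0.2), vcov = diag(0.01, 2)),
                    class = "reduced_fit")
  fits <- list(base, base, base)
  h <- heterogeneity(fits)
  expect_equal(h$Q, 0, tolerance = 1e-12)
  expect_equal(h$I2, 0)
  expect_equal(h$df, 4)
  f2 <- fits
  f2[[3]]$coef <- base$coef + c(0.05, -0.05)
  h2 <- heterogeneity(f2)
  f3 <- fits
  f3[[3]]$coef <- base$coef + 10 * c(0.05, -0.05)
  h3 <- heterogeneity(f3)
  expect_gt(h3$Q, h2$Q)
  expect_null(heterogeneity(fits[1]))
})

test_that("Q calibration under homogeneity", {
  # simulated Psi = 0: Q should fall in the central 95% of its chi-squared
  # reference most of the time (scaled-down calibration: 60 reps)
  p <- 2; k <- 6
  inside <- 0
  for (r in 1:60) {
    fits <- sim_reduced(k, p, rep(0, p), diag(0, p), seed = 100 + r)
    h <- heterogeneity(fits)
    lo <- qchisq(0.025, h$df); hi <- qchisq(0.975, h$df)
    inside <- inside + (h$Q >= lo && h$Q <= hi)
  }
  expect_gte(inside, 0.9 * 60 - 3)
})
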