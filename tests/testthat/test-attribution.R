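# a hand-specified curve on an intercept-complete exposure basis (a
# quadratic B-spline with the full column set represents any quadratic
# exactly): fit basis coefficients to a known parabola so the "true"
# cumulative log RR is analytic
toy_full_spec <- function() {
  s <- toy_exposure_spec()
  basis_spec("bspline_quadratic", s$interior_knots, s$boundary_knots,
             intercept = TRUE)
}

toy_curve <- function(spec = toy_full_spec(), mmt = 22) {
  xs <- seq(spec$boundary_knots[1], spec$boundary_knots[2], length.out = 200)
  target <- 0.002 * (xs - mmt)^2
  B <- evaluate_basis(xs, spec)
  list(coef = qr.solve(B, target), spec = spec, mmt = mmt,
       f = function(x) {
         drop(evaluate_basis(x, spec, extrapolate = TRUE) %*%
                qr.solve(B, target))
       })
}

test_that("percentile table covers 0-100 at 0.1 resolution", {
  pt <- temp_percentile_table(small_city()$temp_mean)
  expect_equal(nrow(pt), 1001L)
  expect_equal(pt$percentile[c(1, 1001)], c(0, 100))
  expect_false(is.unsorted(pt$temp))
})

test_that("find_mmt locates analytic minima, boundaries and ties", {
  s <- small_city()
  pt <- temp_percentile_table(s$temp_mean)
  spec <- toy_full_spec()
  # parabola centered at the 60th-percentile temperature
  t60 <- pt$temp[match(60, pt$percentile)]
  xs <- seq(spec$boundary_knots[1], spec$boundary_knots[2], length.out = 200)
  coef <- qr.solve(evaluate_basis(xs, spec), 0.01 * (xs - t60)^2)
  m <- find_mmt(coef, spec, pt)
  expect_equal(m$mmp, 60, tolerance = 0.02)
  expect_equal(m$mmt, t60, tolerance = 0.05)
  # monotone decreasing curve: boundary clamp at 99
  coef_dec <- qr.solve(evaluate_basis(xs, spec), -0.05 * xs)
  expect_equal(find_mmt(coef_dec, spec, pt)$mmp, 99)
  # flat curve: tie broken toward the median percentile
  expect_equal(find_mmt(rep(0, basis_df(spec)), spec, pt)$mmp, 50)
  expect_error(find_mmt(rep(NaN, basis_df(spec)), spec, pt), "non-finite")
})

test_that("attribute_daily: null curve, closed form, loop oracle", {
  s <- small_city()
  spec <- toy_full_spec()
  vx <- basis_df(spec)
  # flat curve: zero attribution every day
  d0 <- attribute_daily(rep(0, vx), spec, s$temp_mean, s$deaths$total,
                        mmt = 20, max_lag = 25)
  expect_true(all(d0$an == 0))

  # constant series at x0: AN_t = d (1 - exp(-r)) with r the curve at x0
  tc <- toy_curve(spec)
  x0 <- 10; d <- 7
  r <- tc$f(x0) - tc$f(tc$mmt)
  # constant exposure needs mmt inside range; use a two-point range
  temps <- c(rep(tc$mmt, 3), rep(x0, 57))
  cst <- attribute_daily(tc$coef, spec, temps, rep(d, 60), tc$mmt)
  expect_equal(cst$an[4:60], rep(d * (1 - exp(-r)), 57), tolerance = 1e-12)

  # 60-day toy series vs day-by-day loop oracle (winter days: use a curve
  # whose reference sits inside their range)
  tc2 <- toy_curve(spec, mmt = 12)
  temps <- s$temp_mean[1:60]; deaths <- s$deaths$total[1:60]
  dd <- attribute_daily(tc2$coef, spec, temps, deaths, tc2$mmt, max_lag = 5)
  or <- oracle_attribution_loop(tc2$coef, spec, temps, deaths, tc2$mmt,
                                max_lag = 5)
  expect_lt(max(abs(dd$an - or)), 1e-10)
  expect_lt(abs(sum(dd$an) - sum(or)), 1e-10)

  expect_error(attribute_daily(tc$coef, spec, temps, deaths, mmt = 99),
               "outside")
})

test_that("decomposition partitions the total exactly and matches enumeration", {
  spec <- toy_full_spec()
  tc <- toy_curve(spec)
  s <- small_city()
  pt <- temp_percentile_table(s$temp_mean)
  lev <- temperature_levels(pt, tc$mmt)
  daily <- attribute_daily(tc$coef, spec, s$temp_mean, s$deaths$total,
                           tc$mmt, max_lag = 25)
  dec <- decompose_attribution(daily, lev)
  an <- dec$an
  expect_identical(unname(an["cold"] + an["heat"]), unname(an["total"]))
  expect_identical(unname(an["extreme_cold"] + an["moderate_cold"]),
                   unname(an["cold"]))
  expect_identical(unname(an["extreme_heat"] + an["moderate_heat"]),
                   unname(an["heat"]))
  expect_equal(unname(dec$af["total"]), 100 * unname(an["total"]) / dec$deaths)

  # hand enumeration on a 30-day toy
  toy_t <- c(rep(2, 5), rep(10, 10), rep(24, 10), rep(33, 5))
  toy_d <- rep(10, 30)
  lev2 <- list(p1 = 5, mmt = 22, p99 = 30)
  daily2 <- attribute_daily(tc$coef, spec, toy_t, toy_d, 22)
  dec2 <- decompose_attribution(daily2, lev2)
  f <- function(x) tc$f(x) - tc$f(22)
  an_hand <- c(extreme_cold = 5 * 10 * (1 - exp(-f(2))),
               moderate_cold = 10 * 10 * (1 - exp(-f(10))),
               moderate_heat = 10 * 10 * (1 - exp(-f(24))),
               extreme_heat = 5 * 10 * (1 - exp(-f(33))))
  expect_equal(dec2$an[names(an_hand)], an_hand, tolerance = 1e-10)

  # all days on the moderate-heat side only
  hot <- attribute_daily(tc$coef, spec, c(22, rep(25, 29)), toy_d, 22)
  dech <- decompose_attribution(hot, list(p1 = 5, mmt = 22, p99 = 30))
  expect_equal(unname(dech$an["extreme_heat"]), 0)
  expect_equal(unname(dech$an["cold"]), 0)
  expect_equal(unname(dech$an["heat"]), unname(dech$an["total"]))
})

test_that("monte_carlo_eci: degenerate vcov, determinism, PSD guard", {
  spec <- toy_full_spec()
  tc <- toy_curve(spec)
  vx <- basis_df(spec)
  fn <- function(cf) c(stat = sum(cf))
  z <- monte_carlo_eci(tc$coef, matrix(0, vx, vx), fn, n_sim = 200, seed = 1)
  expect_equal(unname(z$low), sum(tc$coef))
  expect_equal(unname(z$high), sum(tc$coef))
  V <- diag(0.01, vx)
  a <- monte_carlo_eci(tc$coef, V, fn, n_sim = 200, seed = 2)
  b <- monte_carlo_eci(tc$coef, V, fn, n_sim = 200, seed = 2)
  expect_identical(a, b)
  expect_error(monte_carlo_eci(tc$coef, V, fn, n_sim = 50), ">= 100")
  Vbad <- V; Vbad[1, 2] <- 0.5 # asymmetric
  expect_error(monte_carlo_eci(tc$coef, Vbad, fn, n_sim = 200), "symmetric")
  Vneg <- diag(c(-0.1, rep(0.01, vx - 1)))
  expect_error(monte_carlo_eci(tc$coef, Vneg, fn, n_sim = 200),
               "positive semi-definite")
})

test_that("attribute_city conserves components per draw and in the eCIs", {
  s <- small_city()
  spec <- toy_full_spec()
  tc <- toy_curve(spec)
  pt <- temp_percentile_table(s$temp_mean)
  mmt <- find_mmt(tc$coef, spec, pt)
  lev <- temperature_levels(pt, mmt$mmt)
  curve <- list(coef = tc$coef, vcov = diag(1e-4, basis_df(spec)),
                exposure_spec = spec)
  res <- attribute_city(curve, s, "total", mmt, lev, max_lag = 25,
                        n_sim = 300, seed = 9)
  tab <- res$table
  get <- function(cmp, col) tab[tab$component == cmp, col]
  expect_equal(get("cold", "an") + get("heat", "an"), get("total", "an"))
  expect_equal(get("extreme_cold", "an") + get("moderate_cold", "an"),
               get("cold", "an"))
  draws <- res$an_draws
  expect_equal(ncol(draws), 4L)
  # af columns are an columns over total deaths
  expect_equal(tab$af, 100 * tab$an / res$deaths)
  expect_equal(tab$af_low, 100 * tab$an_low / res$deaths)
  # RR >= 1 everywhere except at the curve's true minimum: with the exact
  # analytic MMT as reference, every day's AN is non-negative
  daily <- attribute_daily(tc$coef, spec, s$temp_mean, s$deaths$total,
                           tc$mmt, max_lag = 25)
  expect_true(all(daily$an >= -1e-12))
})

test_that("aggregate_cities: ratio invariance and hand arithmetic", {
  mk <- function(an4, deaths, n_sim = 100) {
    anmat <- matrix(rep(an4, each = n_sim), n_sim, 4,
                    dimnames = list(NULL, c("extreme_cold", "moderate_cold",
                                            "moderate_heat", "extreme_heat")))
    point <- list(an = c(an4, cold = an4[1] + an4[2], heat = an4[3] + an4[4],
                         total = sum(an4)),
                  af = NULL, deaths = deaths)
    names(point$an) <- c("extreme_cold", "moderate_cold", "moderate_heat",
                         "extreme_heat", "cold", "heat", "total")
    point$af <- 100 * point$an / deaths
    tempmort:::build_attribution_result("x", "total", NULL, point, anmat)
  }
  a <- mk(c(1, 5, 3, 1), 100)
  # one city: aggregation is the identity on the table
  agg1 <- aggregate_cities(list(a))
  expect_equal(agg1$table$af, a$table$af)
  # two identical cities: pooled AF equals each city's AF
  agg2 <- aggregate_cities(list(a, a))
  expect_equal(agg2$table$af, a$table$af)
  expect_equal(agg2$deaths, 200)
  # three toy cities, hand arithmetic
  b <- mk(c(0, 2, 2, 0), 50); c3 <- mk(c(2, 2, 2, 2), 150)
  agg3 <- aggregate_cities(list(a, b, c3))
  expect_equal(agg3$table$an[agg3$table$component == "total"],
               10 + 4 + 8)
  expect_equal(agg3$table$af[agg3$table$component == "total"],
               100 * 22 / 300)
  # mismatched n_sim
  d <- mk(c(1, 1, 1, 1), 10, n_sim = 50)
  expect_error(aggregate_cities(list(a, d)), "n_sim")
})
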