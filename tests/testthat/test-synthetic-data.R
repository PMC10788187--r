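test_that("spec constructors validate their fields", {
  expect_error(city_climate_spec("a", n_years = 0), "n_years")
  expect_error(city_climate_spec("a", ar_coefficient = 1), "rho")
  expect_error(city_climate_spec("a", seasonal_amplitude = -1), "amplitude")
  expect_error(city_climate_spec("a", pm25_sd = 0), "pm25_sd")
  expect_error(baseline_mortality_spec(0), "> 0")
  expect_error(baseline_mortality_spec(50, dow_effects = rep(0.1, 7)),
               "sum to 0")
  expect_error(risk_surface(function(x) x + 1, rep(0.5, 2), c(0.4, 0.6), 0),
               "curve")
  expect_error(risk_surface(function(x) 0 * x, c(0.5, 0.4), c(0.5, 0.5), 0),
               "sum to 1")
})

test_that("default risk surface honours its invariants", {
  r <- default_risk_surface()
  expect_equal(r$curve(r$true_mmt), 0)
  xs <- seq(-5, 40, by = 0.5)
  expect_true(all(r$curve(xs) >= 0))
  expect_equal(sum(r$cold_shares), 1, tolerance = 1e-12)
  expect_equal(sum(r$heat_shares), 1, tolerance = 1e-12)
  # heat concentrated at lags 0-3, cold spread over the full window
  expect_equal(sum(r$heat_shares[1:4]), 1, tolerance = 1e-12)
  expect_gt(sum(r$cold_shares[5:26]), 0.4)
})

test_that("simulate_temperature: degenerate, moment and determinism contracts", {
  # zero amplitude and noise: constant at the annual mean
  spec0 <- city_climate_spec("a", n_years = 1, seasonal_amplitude = 0,
                             ar_coefficient = 0, daily_sd = 0)
  expect_equal(simulate_temperature(spec0, 1), rep(18.3, 366)) # 2016 is leap
  # law of large numbers at 6 years: sample mean near the annual mean
  spec <- city_climate_spec("a", n_years = 6, annual_mean_temp = 18.3,
                            seasonal_amplitude = 8)
  means <- vapply(1:10, function(s) mean(simulate_temperature(spec, s)), 0)
  expect_lt(max(abs(means - 18.3)), 0.5)
  # determinism
  expect_identical(simulate_temperature(spec, 99),
                   simulate_temperature(spec, 99))
  # calendar length with leap days
  expect_length(simulate_temperature(spec, 1), 2192)
})

test_that("simulate_city: null surface preserves the baseline mean", {
  cl <- city_climate_spec("a", n_years = 6)
  s <- simulate_city(cl, null_risk_surface(), baseline_mortality_spec(50),
                     seed = 3)
  expect_equal(mean(s$deaths$total), 50, tolerance = 0.02)
  expect_length(s$dates, length(s$temp_mean))
  expect_true(all(diff(as.integer(s$dates)) == 1))
})

test_that("strata are multinomial splits that conserve the total", {
  cl <- city_climate_spec("a", n_years = 2)
  s <- simulate_city(cl, default_risk_surface(), baseline_mortality_spec(40),
                     strata_weights = c(male = 0.5, female = 0.5), seed = 4)
  expect_identical(s$deaths$male + s$deaths$female, s$deaths$total)
  # per-stratum surfaces: total is still the sum by construction
  s2 <- simulate_city(cl, default_risk_surface(), baseline_mortality_spec(40),
                      strata_weights = c(male = 0.5, female = 0.5), seed = 4,
                      strata_risk = list(male = default_risk_surface(cold_scale = 0.13)))
  expect_identical(s2$deaths$male + s2$deaths$female, s2$deaths$total)
})

test_that("identical seeds give identical panels", {
  p1 <- reference_panel(seed = 5, n_years = 2)
  p2 <- reference_panel(seed = 5, n_years = 2)
  expect_identical(p1, p2)
  p3 <- reference_panel(seed = 6, n_years = 2)
  expect_false(identical(p1$city_a$deaths$total, p3$city_a$deaths$total))
})

test_that("panel round-trips through CSV exactly", {
  panel <- reference_panel(seed = 8, n_years = 2,
                           strata_weights = c(m = 0.6, f = 0.4))[1:2]
  path <- file.path(withr::local_tempdir(), "panel.csv")
  write_panel(panel, path, truth = list(true_mmt = 25))
  back <- read_panel(path)
  expect_identical(names(back), names(panel))
  for (ct in names(panel)) {
    expect_identical(back[[ct]]$deaths, panel[[ct]]$deaths)
    expect_identical(back[[ct]]$dates, panel[[ct]]$dates)
    expect_lt(max(abs(back[[ct]]$temp_mean - panel[[ct]]$temp_mean)), 1e-9)
    expect_lt(max(abs(back[[ct]]$pm25 - panel[[ct]]$pm25)), 1e-9)
  }
  expect_true(file.exists(paste0(path, ".truth.json")))
})

test_that("read_panel rejects schema violations", {
  panel <- reference_panel(seed = 9, n_years = 2)[1]
  dir <- withr::local_tempdir()
  path <- file.path(dir, "panel.csv")
  write_panel(panel, path)
  dt <- data.table::fread(path)

  gap <- dt[-100, ]
  data.table::fwrite(gap, file.path(dir, "gap.csv"))
  expect_error(read_panel(file.path(dir, "gap.csv")),
               "non-consecutive dates \\(gap between")

  neg <- data.table::copy(dt)
  neg$deaths[5] <- -1
  data.table::fwrite(neg, file.path(dir, "neg.csv"))
  expect_error(read_panel(file.path(dir, "neg.csv")), "non-negative")

  data.table::fwrite(dt[, setdiff(names(dt), "rh"), with = FALSE],
                     file.path(dir, "mis.csv"))
  expect_error(read_panel(file.path(dir, "mis.csv")), "missing column")
})

test_that("null surface: fitted curve amplitude shrinks with series length", {
  # property: regressing null-surface deaths on the cross-basis yields an
  # overall-cumulative curve whose maximum |log RR| shrinks as n grows
  risk <- null_risk_surface()
  amp <- vapply(c(3L, 12L), function(ny) {
    cl <- city_climate_spec("a", n_years = ny)
    s <- simulate_city(cl, risk, baseline_mortality_spec(100), seed = 21)
    f <- fit_city(s, "total", model_spec())
    pt <- f$temp_percentiles
    grid <- pt$temp[pt$percentile >= 1 & pt$percentile <= 99]
    max(abs(predict_curve(f$reduced, grid, median(s$temp_mean))$log_rr))
  }, 0)
  expect_lt(amp[2], amp[1])
})
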