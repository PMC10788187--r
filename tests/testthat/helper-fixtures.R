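# Shared fixtures, built once per test run and memoised in this environment.
# Everything is generated in code from fixed seeds: no stored data files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small single city: 3 years, known surface, moderate counts (fast fits)
small_city <- function(seed = 11L, n_years = 3L,
                       risk = default_risk_surface()) {
  memo(sprintf("city_%d_%d", seed, n_years), {
    simulate_city(city_climate_spec("toy", n_years = n_years),
                  risk, baseline_mortality_spec(50), seed = seed)
  })
}

# reference 4-city panel at reduced scale (4 years) for conservation /
# reproducibility / sensitivity tests
ref_panel_small <- function(seed = 7L, n_years = 4L) {
  memo(sprintf("panel_%d_%d", seed, n_years),
       reference_panel(seed = seed, n_years = n_years))
}

ref_fits <- function(panel = ref_panel_small(), key = "ref_fits") {
  memo(key, lapply(panel, fit_city, stratum = "total", spec = model_spec()))
}

# default exposure spec on a fixed temperature sample
toy_exposure_spec <- function() {
  memo("toy_exposure", {
    x <- small_city()$temp_mean
    basis_spec("bspline_quadratic", quantile_knots(x), range(x))
  })
}
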