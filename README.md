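# tempmort

Two-stage distributed lag non-linear (DLNM) analysis of
temperature–mortality associations for multi-city daily time series, with
attributable-burden decomposition and a fully synthetic validation world.

For environmental epidemiologists studying heat- and cold-related
mortality: the package estimates, per city, the non-linear and delayed
association between daily mean temperature and death counts; pools the city
curves by multivariate random-effects meta-analysis with BLUP shrinkage;
locates each city's minimum mortality temperature (MMT); and decomposes the
deaths attributable to non-optimal temperature into cold/heat and
extreme/moderate components with Monte Carlo empirical confidence intervals
(eCIs). Because mortality registries are rarely public, it ships a
multi-city generator with a known exposure–lag–response surface so the
whole pipeline is testable end to end.

## The model

Stage one, per city *i* (quasi-)Poisson regression:

    log E[Y_it] = α + cb(Temp_it) + ns(RH,4) + ns(PM2.5,4) + ns(O3,4)
                  + ns(t, 8·year) + DOW

`cb(·)` is a cross-basis over lags 0..25: a quadratic B-spline in
temperature (knots at the city's 25th/50th/75th percentiles) crossed with a
natural cubic spline in the lag (knots equally spaced on the log-lag
scale). Coefficients are reduced to the overall cumulative
exposure–response curve and pooled at stage two under
θ_i ~ N(μ, Ψ + S_i), with Ψ estimated by REML. Attribution is backward:
AN_t = Y_t (1 − exp(−[f(x_t) − f(MMT)])), with eCIs from multivariate
normal coefficient draws.

## Worked example

```r
library(tempmort)

# four synthetic cities, 4 years each, known U-shaped surface (true MMT 25)
panel  <- reference_panel(seed = child_seed(1, "panel"), n_years = 4)
bundle <- run_analysis(panel, run_config(n_sim = 1000,
                                         seed = child_seed(1, "run")))
bundle$total$total           # pooled attribution across cities
```

```
<attribution_result> total/total: MMT NA (MMP NA), 596088 deaths
 component        an     an_low   an_high        af     af_low    af_high
      cold 57489.522 41387.7024 72159.757 9.6444689 6.94322020 12.1055544
      heat  1386.496   199.8327  2515.066 0.2325992 0.03352402  0.4219287
     total 58876.018 42652.1716 73631.430 9.8770681 7.15534814 12.3524429
```

Read: on this synthetic panel 9.88% (95% eCI 7.16–12.35%) of deaths are
attributable to non-optimal temperature, almost all of it to cold — the
generator's truth is a cold-dominant burden, and the per-city estimated
MMTs (`vapply(bundle$total$mmts, `[[`, 0, "mmt")` → 23.2, 25.1, 22.8,
26.6 °C) bracket the true 25 °C.

Other entry points: `fit_city()` / `pool_cities()` / `blup()` /
`find_mmt()` / `attribute_city()` for the individual stages,
`run_stratified()` for subgroup analyses (sex, age, education, marital
status), `run_sensitivity()` for the lag/df/pollutant robustness grid,
`write_panel()`/`read_panel()` for the CSV interchange format, and a small
CLI at `inst/cli/tempmort.R` (`simulate`, `run`, `sensitivity`).

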