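#' Configuration for an end-to-end analysis run
#'
#' @param strata strata to analyze (must exist in the input panel).
#' @param meta_method second-stage estimator, `"reml"` or `"mm"`.
#' @param mmt_source curve used for MMT search and attribution: `"blup"`
#'   (default, per-city shrunken curves) or `"pooled"` (fixed effects
#'   applied to every city).
#' @param n_sim Monte Carlo draws for the eCIs.
#' @param seed master seed; child streams are derived with [child_seed()]
#'   so adding a stage never perturbs another stage's draws.
#' @param mmt_range percentile bounds of the MMT search.
#' @param ... [model_spec()] arguments (max_lag, confounder_df,
#'   time_df_per_year, family, include_pm25, include_o3, ...).
#' @return object of class `run_config`.
#' @export
run_config <- function(strata = "total", meta_method = "reml",
                       mmt_source = c("blup", "pooled"), n_sim = 1000L,
                       seed = 1L, mmt_range = c(1, 99), ...) {
  structure(list(strata = strata, meta_method = meta_method,
                 mmt_source = match.arg(mmt_source),
                 n_sim = as.integer(n_sim), seed = as.integer(seed),
                 mmt_range = mmt_range, model = model_spec(...)),
            class = "run_config")
}

analyze_stratum <- function(panel, stratum, config) {
  ms <- config$model
  fits <- lapply(panel, fit_city, stratum = stratum, spec = ms)
  pooled <- pool_cities(fits, method = config$meta_method)
  blups <- blup(pooled, fits)
  results <- vector("list", length(panel))
  names(results) <- names(panel)
  mmts <- vector("list", length(panel))
  for (i in seq_along(panel)) {
    curve <- if (config$mmt_source == "blup") blups[[i]] else
      list(coef = pooled$fixed, vcov = pooled$fixed_vcov,
           exposure_spec = fits[[i]]$reduced$exposure_spec)
    ptab <- fits[[i]]$temp_percentiles
    mmt <- find_mmt(curve$coef, fits[[i]]$reduced$exposure_spec, ptab,
                    range = config$mmt_range)
    lev <- temperature_levels(ptab, mmt$mmt)
    results[[i]] <- attribute_city(curve, panel[[i]], stratum, mmt, lev,
                                   max_lag = ms$max_lag,
                                   n_sim = config$n_sim,
                                   seed = child_seed(config$seed, paste0("mc_", stratum), i))
    mmts[[i]] <- mmt
  }
  list(fits = fits, pooled = pooled, blups = blups, mmts = mmts,
       cities = results, total = aggregate_cities(results))
}

#' Run the two-stage analysis end to end
#'
#' First-stage fits per city and stratum, second-stage pooling with BLUP,
#' MMT search, attribution with Monte Carlo eCIs, and city aggregation.
#' Deterministic given the master seed. If `out_dir` is given, writes
#' `tables/attribution_<stratum>.csv`, `curves/curve_<city>_<stratum>.csv`
#' and `manifest.json`.
#'
#' @param panel named list of `city_series` (or a CSV path readable by
#'   [read_panel()]).
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return named list per stratum: `fits`, `pooled`, `blups`, `mmts`,
#'   `cities` (attribution results), `total` (aggregated).
#' @export
run_analysis <- function(panel, config = run_config(), out_dir = NULL) {
  if (is.character(panel)) panel <- read_panel(panel)
  for (st in config$strata)
    for (s in panel)
      if (is.null(s$deaths[[st]]))
        stopf("stratum '%s' absent from city %s", st, s$city_id)
  bundle <- list()
  for (st in config$strata) {
    res <- tryCatch(analyze_stratum(panel, st, config), error = function(e)
      stopf("stage failure in stratum '%s': %s", st, conditionMessage(e)))
    bundle[[st]] <- res
  }
  if (!is.null(out_dir)) write_results(bundle, panel, config, out_dir)
  invisible(bundle)
}

#' Run stratified analyses with failure isolation
#'
#' Independent first-stage fits, pooling and attribution per stratum. A
#' stratum whose fit fails (e.g. all-zero counts) is skipped with a warning
#' and reported in `$failed`; other strata are unaffected.
#'
#' @param panel named list of `city_series`.
#' @param config a [run_config()]; its `strata` field lists the strata.
#' @return list with `strata` (per-stratum bundles), `failed` (named error
#'   messages), and `conservation` (per complementary pair, whether stratum
#'   deaths sum to the total).
#' @export
run_stratified <- function(panel, config) {
  out <- list(); failed <- character()
  for (st in config$strata) {
    res <- tryCatch(analyze_stratum(panel, st, config), error = function(e) e)
    if (inherits(res, "error")) {
      warnf("stratum '%s' failed: %s", st, conditionMessage(res))
      failed[st] <- conditionMessage(res)
    } else out[[st]] <- res
  }
  cons <- lapply(panel, function(s) {
    strata <- setdiff(names(s$deaths), "total")
    if (!length(strata)) return(NA)
    all(Reduce(`+`, s$deaths[strata]) == s$deaths$total)
  })
  list(strata = out, failed = failed, conservation = cons)
}

#' Sensitivity analysis grid
#'
#' @param max_lag maximum lag values.
#' @param time_df time-spline df per year values.
#' @param confounder_df confounder-spline df values.
#' @param pollutants pollutant adjustment sets.
#' @return data.frame, one row per configuration (the first row is the
#'   baseline: lag 25, time df 8, confounder df 4, both pollutants).
#' @export
sensitivity_grid <- function(max_lag = c(25L, 21L), time_df = c(8L, 7L, 9L),
                             confounder_df = c(4L, 3L, 5L),
                             pollutants = c("both", "none", "pm25", "o3")) {
  g <- expand.grid(pollutants = pollutants, confounder_df = confounder_df,
                   time_df = time_df, max_lag = max_lag,
                   stringsAsFactors = FALSE)
  g[, c("max_lag", "time_df", "confounder_df", "pollutants")]
}

#' Run the sensitivity grid
#'
#' Re-runs the full pipeline (total stratum) for each configuration and
#' collects the pooled attributable fractions; configurations whose total AF
#' deviates from the baseline row by more than `flag_threshold` percentage
#' points are flagged. Individual configuration failures are recorded and
#' the grid continues.
#'
#' @param panel named list of `city_series`.
#' @param config baseline [run_config()].
#' @param grid a [sensitivity_grid()].
#' @param flag_threshold percentage-point deviation that triggers a flag.
#' @return data.frame: one row per configuration x component with `af`,
#'   `af_low`, `af_high`, plus `error` and `flagged` columns.
#' @export
run_sensitivity <- function(panel, config, grid = sensitivity_grid(),
                            flag_threshold = 2.5) {
  if (!nrow(grid)) stopf("empty sensitivity grid")
  rows <- list()
  base_af <- NA_real_
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cfg <- run_config(strata = "total", meta_method = config$meta_method,
                      mmt_source = config$mmt_source, n_sim = config$n_sim,
                      seed = config$seed, mmt_range = config$mmt_range,
                      max_lag = g$max_lag, time_df_per_year = g$time_df,
                      confounder_df = g$confounder_df,
                      include_pm25 = g$pollutants %in% c("both", "pm25"),
                      include_o3 = g$pollutants %in% c("both", "o3"),
                      family = config$model$family)
    res <- tryCatch(run_analysis(panel, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(g, component = NA, af = NA, af_low = NA,
                              af_high = NA, error = conditionMessage(res),
                              row.names = NULL)
      next
    }
    tab <- res$total$total$table
    if (i == 1) base_af <- tab$af[tab$component == "total"]
    rows[[i]] <- data.frame(g[rep(1, nrow(tab)), ], component = tab$component,
                            af = tab$af, af_low = tab$af_low,
                            af_high = tab$af_high, error = NA_character_,
                            row.names = NULL)
  }
  out <- do.call(rbind, rows)
  tot <- out$component == "total" & is.na(out$error)
  out$flagged <- FALSE
  out$flagged[tot] <- abs(out$af[tot] - base_af) > flag_threshold
  out
}

attribution_table_dt <- function(res_stratum) {
  rows <- c(res_stratum$cities, list(total = res_stratum$total))
  data.table::rbindlist(lapply(rows, function(r) {
    wide <- as.list(unlist(lapply(seq_len(nrow(r$table)), function(j) {
      v <- r$table[j, c("an", "an_low", "an_high", "af", "af_low", "af_high")]
      stats::setNames(as.numeric(v),
                      paste0(c("an", "an_low", "an_high", "af", "af_low",
                               "af_high"), "_", r$table$component[j]))
    })))
    c(list(city = r$city_id, stratum = r$stratum, mmp = r$mmp, mmt = r$mmt,
           deaths = r$deaths), wide)
  }), fill = TRUE)
}

write_results <- function(bundle, panel, config, out_dir) {
  dir.create(file.path(out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "curves"), recursive = TRUE,
             showWarnings = FALSE)
  manifest <- list(seed = config$seed, n_sim = config$n_sim,
                   strata = config$strata, meta_method = config$meta_method,
                   mmt_source = config$mmt_source,
                   model = unclass(config$model), knots = list())
  for (st in names(bundle)) {
    res <- bundle[[st]]
    data.table::fwrite(attribution_table_dt(res),
                       file.path(out_dir, "tables",
                                 sprintf("attribution_%s.csv", st)))
    for (ct in names(res$cities)) {
      fit <- res$fits[[which(names(res$cities) == ct)]]
      ptab <- fit$temp_percentiles
      grid <- ptab$temp[ptab$percentile >= 1 & ptab$percentile <= 99]
      curve <- predict_curve(res$blups[[ct]], grid,
                             center = res$mmts[[which(names(res$cities) == ct)]]$mmt)
      data.table::fwrite(
        data.table::data.table(temp = curve$temp, rr = curve$rr,
                               rr_low = curve$rr_low,
                               rr_high = curve$rr_high),
        file.path(out_dir, "curves", sprintf("curve_%s_%s.csv", ct, st)))
      manifest$knots[[paste(ct, st, sep = "/")]] <- list(
        exposure = fit$cb_spec$exposure_spec$interior_knots,
        exposure_boundary = fit$cb_spec$exposure_spec$boundary_knots,
        lag = fit$cb_spec$lag_spec$interior_knots,
        dispersion = fit$dispersion, n_days = fit$n_days_used)
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
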