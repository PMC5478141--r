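#' Per-country exposure for a set of scenarios
#'
#' Chains the exposure stages for one or more scenarios sharing a
#' historical reference: regrid each model to the common grid, ensemble
#' mean, window mean, anomaly against the reference climatology, and EEZ
#' zonal means. Model runs are regridded and ensemble-averaged once per
#' RCP and reused across projection windows.
#'
#' @param models_by_rcp Named list (`"2.6"`, `"4.5"`, `"8.5"`) of lists of
#'   per-model [gridded_series()] scenario runs.
#' @param historical List of per-model [gridded_series()] historical runs.
#' @param regions List of `eez_region` from [merge_by_sovereignty()].
#' @param scenarios List of [scenario_spec()]; default all six canonical
#'   scenarios restricted to the RCPs supplied.
#' @param target Common [grid_spec()]; default the first model's grid.
#' @return List with `e1` (named list per scenario label of
#'   [zonal_means()] tables) and `anomalies` (named list of [anomaly()]
#'   fields).
#' @export
compute_exposure <- function(models_by_rcp, historical, regions,
                             scenarios = NULL,
                             target = historical[[1]]$grid) {
  if (is.null(scenarios)) {
    scenarios <- Filter(function(s) sprintf("%.1f", s$rcp) %in%
                          names(models_by_rcp), scenario_grid())
  }
  hist_ens <- ensemble_mean(lapply(historical, regrid_to_common,
                                   target = target))
  e1 <- list(); anoms <- list()
  for (key in names(models_by_rcp)) {
    ens <- ensemble_mean(lapply(models_by_rcp[[key]], regrid_to_common,
                                target = target))
    n_mod <- length(models_by_rcp[[key]])
    for (sc in scenarios) {
      if (sprintf("%.1f", sc$rcp) != key) next
      ref_map <- window_mean(hist_ens, sc$reference)
      an <- anomaly(window_mean(ens, sc$window), ref_map, target, sc,
                    n_models = n_mod)
      lbl <- scenario_label(sc)
      anoms[[lbl]] <- an
      e1[[lbl]] <- zonal_means(an, regions)
    }
  }
  list(e1 = e1, anomalies = anoms)
}

# classification flag column as logical, FALSE when the column is absent
.flag <- function(rec, name) {
  if (is.null(rec[[name]])) return(rep(FALSE, nrow(rec)))
  v <- as.logical(rec[[name]])
  v & !is.na(v)
}

#' Group summaries for one vulnerability table
#'
#' @param vt A [vulnerability_index()] table (typically the focal
#'   scenario, RCP 8.5 / 2016--2050).
#' @param records Raw country table carrying `ldc`, `oecd`, `sids`,
#'   `continent` and optionally `co2_per_capita`.
#' @return List: `economic` ([quartile_crosstab()] for LDC and OECD),
#'   `geographic` ([geography_crosstab()]), `emissions`
#'   ([emissions_correlation()], `NULL` without emissions data),
#'   `sids_in_top10` count, `ldc_top_half`/`oecd_bottom_half` fractions.
#' @export
group_reports <- function(vt, records) {
  rec <- records[match(vt$country, records$country), ]
  ldc <- rec$country[.flag(rec, "ldc")]
  oecd <- rec$country[.flag(rec, "oecd")]
  sids <- rec$country[.flag(rec, "sids")]
  if (is.null(rec$continent)) rec$continent <- "other"
  emis <- NULL
  if ("co2_per_capita" %in% names(rec) &&
      sum(!is.na(rec$co2_per_capita)) >= 3)
    emis <- emissions_correlation(
      vt, stats::setNames(rec$co2_per_capita, rec$country),
      ldc = ldc, oecd = oecd)
  top10 <- vt$country[vt$rank <= 10L]
  list(economic = quartile_crosstab(vt, list(LDC = ldc, OECD = oecd)),
       geographic = geography_crosstab(
         vt, stats::setNames(rec$continent, rec$country)),
       emissions = emis,
       sids_in_top10 = sum(top10 %in% sids),
       ldc_top_half = top_half_share(vt, ldc),
       oecd_bottom_half = 1 - top_half_share(vt, oecd))
}

#' Vulnerability study from country records and exposure tables
#'
#' The analysis half of the pipeline: assemble indicators, apply the
#' exclusion policy consistently across scenarios (a country excluded
#' anywhere is excluded everywhere, so all six tables share one country
#' set), compute the six vulnerability tables and the group reports for
#' the focal scenario.
#'
#' @param records Raw country table ([read_country_table()] schema).
#' @param e1_by_scenario Named list of [zonal_means()] tables.
#' @param focal Label of the scenario used for the group reports (default
#'   `"rcp8.5_2016-2050"`, falling back to the first available).
#' @param policy Exclusion policy, see [build_indicator_table()].
#' @return List: `indicators`, `exclusions`, `tables` (one
#'   [vulnerability_index()] per scenario), `reports`, `extremes`
#'   ([scenario_extremes()]), `focal`.
#' @export
run_country_study <- function(records, e1_by_scenario,
                              focal = "rcp8.5_2016-2050",
                              policy = "complete_case") {
  stopifnot(length(e1_by_scenario) > 0)
  # a country with missing exposure in any scenario is dropped from all
  excluded_anywhere <- unique(unlist(lapply(e1_by_scenario, function(t)
    t$country[t$excluded])))
  base_e1 <- e1_by_scenario[[1]]
  base_e1$excluded <- base_e1$excluded |
    base_e1$country %in% excluded_anywhere
  built <- build_indicator_table(records, base_e1, policy = policy)
  keep <- built$indicators$country
  socio <- built$indicators[, c("country", paste0("S", 1:5),
                                paste0("AC", 1:6))]
  e1_kept <- lapply(e1_by_scenario, function(t)
    t[t$country %in% keep, , drop = FALSE])
  tables <- run_scenarios(socio, e1_kept)
  if (!focal %in% names(tables)) focal <- names(tables)[1]
  vt <- tables[[focal]]
  list(indicators = built$indicators, exclusions = built$exclusions,
       tables = tables,
       reports = group_reports(vt, records),
       extremes = scenario_extremes(
         tables, k = 5L,
         sids = records$country[.flag(records, "sids")],
         oecd = records$country[.flag(records, "oecd")]),
       focal = focal)
}

#' Run the full pipeline on synthetic inputs
#'
#' Generates the synthetic world (climate, EEZs, country table) from a
#' [synth_config()], computes exposure for the requested RCPs and windows,
#' and runs the vulnerability study. This is the end-to-end entry point
#' used by the analysis scripts and the acceptance checks.
#'
#' @param cfg A [synth_config()].
#' @param rcps RCPs to run (default all three).
#' @param keep_anomalies Keep the gridded anomaly fields in the result
#'   (default `TRUE`; set `FALSE` to save memory).
#' @return The [run_country_study()] result plus `config`, `records`,
#'   `labels`, `e1` and optionally `anomalies`.
#' @export
run_synthetic_study <- function(cfg = synth_config(),
                                rcps = c(2.6, 4.5, 8.5),
                                keep_anomalies = TRUE) {
  regions <- merge_by_sovereignty(gen_eezs(cfg))
  historical <- gen_climate(cfg)
  target <- historical[[1]]$grid
  hist_ens <- ensemble_mean(historical)
  rm(historical)
  e1 <- list(); anoms <- list()
  ref_cache <- list()
  for (r in rcps) {
    models <- gen_climate(cfg, r)
    ens <- ensemble_mean(models)
    n_mod <- length(models)
    rm(models)
    for (sc in scenario_grid()) {
      if (sc$rcp != r) next
      rk <- paste(sc$reference, collapse = "-")
      if (is.null(ref_cache[[rk]]))
        ref_cache[[rk]] <- window_mean(hist_ens, sc$reference)
      an <- anomaly(window_mean(ens, sc$window), ref_cache[[rk]], target,
                    sc, n_models = n_mod)
      lbl <- scenario_label(sc)
      anoms[[lbl]] <- an
      e1[[lbl]] <- zonal_means(an, regions)
    }
  }
  gi <- gen_indicators(cfg)
  out <- run_country_study(gi$records, e1)
  out$config <- cfg
  out$records <- gi$records
  out$labels <- gi$labels
  out$e1 <- e1
  if (keep_anomalies) out$anomalies <- anoms
  out
}

#' Rerun the published-style analysis from user-supplied tables
#'
#' Runs the index on a real country table (the supplementary-data schema
#' of the original study, adapted via `col_map`) and per-country anomaly
#' tables, one CSV per scenario with columns `country`, `anomaly_degC`.
#' The package ships no real data; obtaining the country spreadsheet and
#' anomaly extractions is the user's task.
#'
#' @param country_csv Path to the raw country table CSV.
#' @param e1_csvs Named character vector of anomaly CSV paths, names being
#'   scenario labels such as `"rcp8.5_2016-2050"`.
#' @param col_map Optional column mapping for [read_country_table()].
#' @param ... Passed to [run_country_study()].
#' @return A [run_country_study()] result.
#' @export
reproduce_published_analysis <- function(country_csv, e1_csvs,
                                         col_map = NULL, ...) {
  records <- read_country_table(country_csv, col_map = col_map)
  e1 <- lapply(e1_csvs, function(p) {
    t <- utils::read.csv(p, stringsAsFactors = FALSE)
    if (!all(c("country", "anomaly_degC") %in% names(t)))
      stop("anomaly table needs columns country, anomaly_degC",
           call. = FALSE)
    if (is.null(t$excluded)) t$excluded <- is.na(t$anomaly_degC)
    t
  })
  run_country_study(records, e1, ...)
}
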