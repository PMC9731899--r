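#' Default end-to-end pipeline configuration
#'
#' The study conditions of the packaged synthetic analysis: a 20 x 20 grid
#' of 927 m cells, 8 stations, 2 calendar years, predictor informativeness
#' 0.8, 10% hourly missingness.  `n_candidates` controls the size of the
#' Latin-hypercube tuning design (the full-study design used 25; the
#' default here trades a denser search for minutes-scale runs without
#' changing the data conditions).
#'
#' @param ... overrides for any field.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(n_row = 20, n_col = 20, cell_size = 927, n_stations = 8,
              start_year = 2012, n_years = 2, n_polygons = 6,
              total_population = 1e6, peak_hour = 10,
              informativeness = 0.8, missingness = 0.1, noise_sd = 0.3,
              temperature_coupling = 0.15, n_candidates = 10,
              min_hours = 18, annual_limit = 10, daily_limit = 41,
              rain_threshold = 1, temp_threshold = 20, nthread = 1)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full exposure pipeline
#'
#' Simulate -> ingest -> features -> tune -> leave-one-station-out CV ->
#' final models -> surfaces -> exposure applications, writing plain-text
#' report files.  Every source of randomness derives from `seed`, so two
#' runs with the same seed and configuration produce byte-identical
#' reports.
#'
#' Files written to `out_dir`: `metrics_mean.csv`, `metrics_max.csv`
#' (overall / per-year / per-season CV metrics), `compliance.json`,
#' `ratio_groups.csv`, `heat.json`, `areal_bins.csv`, `summary.json`.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed.
#' @param config list from [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`cv_mean`,
#'   `cv_max`, `compliance`, `ratio`, `heat`, `areal`, `files`).
#' @export
run_pipeline <- function(out_dir, seed = 1, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  fixture <- make_region_fixture(
    n_row = cfg$n_row, n_col = cfg$n_col, cell_size = cfg$cell_size,
    n_stations = cfg$n_stations, start_year = cfg$start_year,
    n_years = cfg$n_years, n_polygons = cfg$n_polygons,
    total_population = cfg$total_population, seed = seed)
  truth <- make_truth_field(fixture, peak_hour = cfg$peak_hour,
                            temperature_coupling = cfg$temperature_coupling,
                            seed = seed + 1)
  records <- simulate_observations(fixture, truth,
                                   missingness = cfg$missingness,
                                   noise_sd = cfg$noise_sd, seed = seed + 2)
  predictors <- simulate_predictors(fixture, truth,
                                    informativeness = cfg$informativeness,
                                    seed = seed + 3)
  station_days <- aggregate_station_days(records, min_hours = cfg$min_hours)
  candidates <- sample_hyperparameters(cfg$n_candidates, seed = seed + 4)

  cv_mean <- loso_cv(fixture, station_days, predictors, "mean", candidates,
                     seed = seed + 5, nthread = cfg$nthread)
  cv_max <- loso_cv(fixture, station_days, predictors, "max", candidates,
                    seed = seed + 6, nthread = cfg$nthread)

  files <- character(0)
  wcsv <- function(d, name) {
    f <- file.path(out_dir, name)
    utils::write.csv(d, f, row.names = FALSE)
    files <<- c(files, f)
  }
  wjson <- function(x, name) {
    f <- file.path(out_dir, name)
    jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <<- c(files, f)
  }
  metr <- function(cv) dplyr::bind_rows(stratify_metrics(cv, "overall"),
                                        stratify_metrics(cv, "year"),
                                        stratify_metrics(cv, "season"))
  wcsv(metr(cv_mean), "metrics_mean.csv")
  wcsv(metr(cv_max), "metrics_max.csv")

  # Final models: one more station-wise tuning on all stations, then fit on
  # everything and predict every cell-day.
  fit_final <- function(target, s) {
    feats <- suppressMessages(
      training_features(fixture, station_days, predictors, target))
    hp <- tune_hyperparameters(feats, candidates, seed = s,
                               nthread = cfg$nthread)
    fit_exposure_model(feats, hp = hp, target_kind = target, seed = s,
                       nthread = cfg$nthread)
  }
  model_mean <- fit_final("mean", seed + 7)
  model_max <- fit_final("max", seed + 8)
  surf_mean <- suppressMessages(
    predict_surface(model_mean, fixture, station_days, predictors))
  surf_max <- suppressMessages(
    predict_surface(model_max, fixture, station_days, predictors))
  surf_idw <- suppressMessages(
    idw_surface(fixture, station_days, "mean"))

  populations <- populate_cells(fixture)
  year <- cfg$start_year
  compliance <- compliance_report(
    surf_mean, populations,
    limits = c(annual = cfg$annual_limit, daily = cfg$daily_limit),
    year = year, comparison = surf_idw)
  wjson(unclass_deep(compliance), "compliance.json")

  ratio <- daily_ratio_series(surf_mean, surf_max,
                              predictors$precipitation, predictors$dates,
                              rain_threshold = cfg$rain_threshold,
                              season_filter = "rainy")
  wcsv(ratio$group_means, "ratio_groups.csv")

  tmean <- (predictors$tmax + predictors$tmin) / 2
  di <- match(surf_mean$dates, predictors$dates)
  heat <- heat_cooccurrence(surf_mean, tmean[, di, drop = FALSE],
                            daily_limit = cfg$daily_limit,
                            temp_threshold = cfg$temp_threshold)
  wjson(heat[setdiff(names(heat), "conditional_quartiles")], "heat.json")

  areal <- areal_link(surf_mean, fixture, year = year)
  wcsv(areal$bins, "areal_bins.csv")

  ecdf <- population_ecdf(surf_mean, populations, year)
  mm <- compute_metrics(cv_mean$predictions$observed,
                        cv_mean$predictions$predicted)
  mx <- compute_metrics(cv_max$predictions$observed,
                        cv_max$predictions$predicted)
  wjson(list(
    seed = seed,
    n_station_days = nrow(station_days),
    loso = list(mean = as.list(mm), max = as.list(mx)),
    exposure = list(
      person_days = compliance$person_days,
      person_days_idw = compliance$comparison$person_days,
      frac_above_annual = compliance$frac_above_annual,
      tau_temperature = heat$tau,
      tau_marginalization = areal$tau,
      ecdf_p10 = ecdf_quantile(ecdf, 0.1))), "summary.json")

  invisible(list(fixture = fixture, truth = truth,
                 station_days = station_days,
                 cv_mean = cv_mean, cv_max = cv_max,
                 surf_mean = surf_mean, surf_max = surf_max,
                 surf_idw = surf_idw, compliance = compliance,
                 ratio = ratio, heat = heat, areal = areal, ecdf = ecdf,
                 files = files))
}

# Strip S3 classes recursively so jsonlite serialises plainly.
unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}
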