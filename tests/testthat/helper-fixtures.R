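# Shared simulated datasets, built once per test run.

.sim_cache <- new.env(parent = emptyenv())

# The default study conditions: 20x20 grid, 8 stations, 2 years,
# informativeness 0.8, seed chain from 1.
default_sim <- function() {
  if (is.null(.sim_cache$default)) {
    fixture <- make_region_fixture(seed = 1)
    truth <- make_truth_field(fixture, seed = 2)
    records <- simulate_observations(fixture, truth, seed = 3)
    predictors <- simulate_predictors(fixture, truth,
                                      informativeness = 0.8, seed = 4)
    station_days <- aggregate_station_days(records)
    .sim_cache$default <- list(fixture = fixture, truth = truth,
                               records = records, predictors = predictors,
                               station_days = station_days)
  }
  .sim_cache$default
}

# A small, fast variant for structural unit tests.
small_sim <- function() {
  if (is.null(.sim_cache$small)) {
    fixture <- make_region_fixture(n_row = 8, n_col = 8, n_stations = 4,
                                   n_years = 1, n_polygons = 3,
                                   total_population = 1e5, seed = 21)
    truth <- make_truth_field(fixture, seed = 22)
    records <- simulate_observations(fixture, truth, seed = 23)
    predictors <- simulate_predictors(fixture, truth,
                                      informativeness = 0.8, seed = 24)
    station_days <- aggregate_station_days(records)
    .sim_cache$small <- list(fixture = fixture, truth = truth,
                             records = records, predictors = predictors,
                             station_days = station_days)
  }
  .sim_cache$small
}

# Bare exposure surface from a matrix.
make_surface <- function(values, dates, cell_id = seq_len(nrow(values)),
                         target = "mean") {
  structure(list(values = values, cell_id = cell_id, dates = dates,
                 target = target),
            class = "exposure_surface")
}

# Minimal hand-built fixture for population/areal toys: a row of square
# cells of side `cell_size` with centroids at given coordinates.
toy_fixture <- function(cx, cy, cell_size, raster) {
  structure(list(
    grid = tibble::tibble(cell_id = seq_along(cx), row = 1L,
                          col = seq_along(cx), x = cx, y = cy,
                          elevation = 2250),
    cell_size = cell_size, n_row = 1L, n_col = length(cx),
    stations = tibble::tibble(), polygons = list(),
    population = raster,
    dates = as.Date("2012-01-01"), seed = 0L), class = "region_fixture")
}

hourly_day <- function(station, date, hours, values) {
  tibble::tibble(station_id = station, date = as.Date(date),
                 hour = hours, pm25 = values)
}
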