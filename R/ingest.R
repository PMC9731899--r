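#' Aggregate hourly records into station-day targets
#'
#' Groups hourly PM2.5 records by station and UTC-6 civil day and emits the
#' daily mean and daily 1-h maximum, keeping only station-days with at least
#' `min_hours` distinct observed hours (default 18); all other station-days
#' are discarded.  Timestamps are taken to be UTC-6 by contract and no
#' daylight-saving shift is ever applied.
#'
#' "18 h of observations" counts distinct hours carrying a valid value, not
#' wall-clock span.
#'
#' @param records tibble/data.frame with columns `station_id`, `date`
#'   (`Date`), `hour` (integer 0-23), `pm25` (ug/m^3, non-negative finite).
#' @param min_hours completeness threshold (hours per day).
#' @return Tibble of station-days: `station_id`, `date`, `mean_pm25`,
#'   `max_pm25`, `n_hours`, ordered by station then date.
#' @examples
#' rec <- tibble::tibble(station_id = "A", date = as.Date("2012-01-15"),
#'                       hour = 0:23, pm25 = 1:24)
#' aggregate_station_days(rec)  # mean 12.5, max 24
#' @export
aggregate_station_days <- function(records, min_hours = 18) {
  stopifnot(all(c("station_id", "date", "hour", "pm25") %in% names(records)),
            min_hours >= 1)
  if (any(!is.finite(records$pm25) | records$pm25 < 0)) {
    stop("negative or non-finite pm25 concentration")
  }
  if (any(records$hour < 0 | records$hour > 23)) stop("hour outside 0-23")
  if (anyDuplicated(records[c("station_id", "date", "hour")])) {
    stop("duplicate (station, timestamp) pairs: ambiguous observation")
  }
  out <- records |>
    dplyr::group_by(.data$station_id, .data$date) |>
    dplyr::summarise(mean_pm25 = mean(.data$pm25),
                     max_pm25 = max(.data$pm25),
                     n_hours = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_hours >= min_hours) |>
    dplyr::arrange(.data$station_id, .data$date)
  out
}

#' Assign the local season of a date
#'
#' Seasons follow the study region's three-season climatology: cold dry
#' (November-February), warm dry (March-May), rainy (June-October).
#'
#' @param date a `Date` vector.
#' @return Character vector with values `"cold_dry"`, `"warm_dry"`,
#'   `"rainy"`.
#' @examples
#' assign_season(as.Date(c("2012-01-15", "2012-03-01", "2012-10-31")))
#' @export
assign_season <- function(date) {
  m <- month_of(date)
  ifelse(m %in% c(11, 12, 1, 2), "cold_dry",
         ifelse(m %in% 3:5, "warm_dry", "rainy"))
}

#' Most frequent daily peak hour
#'
#' For each retained station-day (the same completeness rule as
#' [aggregate_station_days()]), finds the hour of the greatest hourly
#' concentration (earliest hour on exact ties), then returns the mode of
#' those peak hours across station-days (again the earliest hour if modes
#' tie).  This is the statistic behind choosing a mid-morning snapshot hour
#' for the daily-max model's sub-daily predictors.
#'
#' @inheritParams aggregate_station_days
#' @return Integer hour of day, 0-23.
#' @export
modal_peak_hour <- function(records, min_hours = 18) {
  peaks <- records |>
    dplyr::group_by(.data$station_id, .data$date) |>
    dplyr::summarise(
      n_hours = dplyr::n(),
      peak = .data$hour[which.max(.data$pm25)],  # which.max: earliest tie
      .groups = "drop") |>
    dplyr::filter(.data$n_hours >= min_hours)
  if (nrow(peaks) == 0) stop("no retained station-day")
  tab <- table(factor(peaks$peak, levels = 0:23))
  as.integer(names(tab)[which.max(tab)])
}

#' Read hourly station records from CSV
#'
#' Reads the delimited format written by [write_fixture()]: columns
#' `station_id`, `date` (ISO), `hour`, `pm25`.  Alternatively a `timestamp`
#' column `"YYYY-MM-DD HH:MM"` is accepted.  Timestamps are UTC-6 civil time
#' by contract; timezone-annotated timestamps (a trailing `Z` or a UTC
#' offset) are refused rather than converted.
#'
#' @param path CSV file path.
#' @return Tibble with columns `station_id`, `date`, `hour`, `pm25`.
#' @export
read_hourly_records <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("timestamp" %in% names(d)) {
    ts <- trimws(d$timestamp)
    if (any(grepl("(Z|[+-][0-9]{2}:?[0-9]{2})$", ts))) {
      stop("timezone-annotated timestamps refused: records must be UTC-6 civil time")
    }
    d$date <- as.Date(substr(ts, 1, 10))
    d$hour <- as.integer(substr(ts, 12, 13))
    d$timestamp <- NULL
  }
  stopifnot(all(c("station_id", "date", "hour", "pm25") %in% names(d)))
  d$date <- as.Date(d$date)
  tibble::as_tibble(d)
}

#' Write a fixture and its simulated data to plain-text files
#'
#' Writes `stations.csv`, `grid.csv`, `hourly_records.csv`,
#' `population.csv` (raster in long form), `polygons.geojson` (with a
#' `marginalization` property per feature), optionally `predictors.csv`
#' (long form: `cell_id`, `date`, `variable`, `value`), and `config.yaml`
#' recording sizes and seed.
#'
#' @param fixture a [make_region_fixture()] object.
#' @param records optional tibble from [simulate_observations()].
#' @param predictors optional [simulate_predictors()] object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_fixture <- function(fixture, records = NULL, predictors = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wf <- function(d, name) {
    f <- file.path(dir, name)
    utils::write.csv(d, f, row.names = FALSE)
    files <<- c(files, f)
  }
  wf(fixture$stations, "stations.csv")
  wf(fixture$grid, "grid.csv")
  if (!is.null(records)) wf(records, "hourly_records.csv")
  p <- fixture$population
  pop_long <- data.frame(
    ix = rep(seq_len(p$nx), times = p$ny),
    iy = rep(seq_len(p$ny), each = p$nx),
    x = p$x0 + (rep(seq_len(p$nx), times = p$ny) - 0.5) * p$dx,
    y = p$y0 + (rep(seq_len(p$ny), each = p$nx) - 0.5) * p$dy,
    density = as.vector(p$density)
  )
  wf(pop_long, "population.csv")

  feats <- lapply(fixture$polygons, function(pg) {
    ring <- rbind(pg$xy, pg$xy[1, ])
    list(type = "Feature",
         properties = list(unit_id = pg$unit_id,
                           marginalization = pg$marginalization),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  gj <- file.path(dir, "polygons.geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       gj, auto_unbox = TRUE, digits = NA)
  files <- c(files, gj)

  if (!is.null(predictors)) {
    layers <- setdiff(names(predictors), c("dates", "cell_id", "road_density"))
    long <- do.call(rbind, lapply(layers, function(nm) {
      data.frame(cell_id = rep(predictors$cell_id, length(predictors$dates)),
                 date = rep(as.character(predictors$dates),
                            each = length(predictors$cell_id)),
                 variable = nm, value = as.vector(predictors[[nm]]))
    }))
    long <- rbind(long, data.frame(cell_id = predictors$cell_id, date = NA,
                                   variable = "road_density",
                                   value = predictors$road_density))
    wf(long, "predictors.csv")
  }

  cfg <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(
    n_row = fixture$n_row, n_col = fixture$n_col,
    cell_size = fixture$cell_size, n_cells = nrow(fixture$grid),
    n_stations = nrow(fixture$stations),
    n_polygons = length(fixture$polygons),
    dates = list(start = as.character(min(fixture$dates)),
                 end = as.character(max(fixture$dates))),
    seed = fixture$seed), cfg)
  files <- c(files, cfg)
  invisible(files)
}
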