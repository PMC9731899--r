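#' Predict an exposure surface over the grid
#'
#' Applies a fitted model to every in-region cell and requested day,
#' producing the per-cell per-day concentration surface that all exposure
#' applications consume.  Days on which no station reported (undefined IDW
#' baseline) are dropped with a message.
#'
#' @param model an [fit_exposure_model()] object.
#' @param fixture a [make_region_fixture()] object.
#' @param station_days tibble from [aggregate_station_days()] (the IDW
#'   sources).
#' @param predictors a [simulate_predictors()] object.
#' @param dates days to predict (default all).
#' @param idw_exponent IDW distance exponent.
#' @return Object of class `exposure_surface`: list with `values` (cells x
#'   days matrix, ug/m^3), `cell_id`, `dates`, `target`.
#' @export
predict_surface <- function(model, fixture, station_days, predictors,
                            dates = NULL, idw_exponent = 2) {
  stopifnot(inherits(model, "exposure_model"))
  feats <- prediction_features(fixture, station_days, predictors,
                               target = model$target_kind, dates = dates,
                               idw_exponent = idw_exponent)
  feats$predicted <- predict(model, feats)
  surface_from_rows(feats, fixture, model$target_kind)
}

#' IDW-only exposure surface
#'
#' The comparison surface: per cell-day, the plain IDW interpolation of
#' same-day station observations with no learned component.
#'
#' @inheritParams predict_surface
#' @param target `"mean"` or `"max"`.
#' @return An `exposure_surface`.
#' @export
idw_surface <- function(fixture, station_days, target = c("mean", "max"),
                        dates = NULL, idw_exponent = 2) {
  target <- match.arg(target)
  dates <- dates %||% sort(unique(station_days$date))
  sources <- station_day_sources(fixture, station_days, target)
  nc <- nrow(fixture$grid)
  rows <- tibble::tibble(
    cell_id = rep(fixture$grid$cell_id, length(dates)),
    x = rep(fixture$grid$x, length(dates)),
    y = rep(fixture$grid$y, length(dates)),
    date = rep(dates, each = nc))
  rows$predicted <- idw_from_station_days(rows, sources,
                                          exponent = idw_exponent)
  drop <- !is.finite(rows$predicted)
  if (any(drop)) {
    message(sum(drop), " cell-day(s) dropped: no same-day observations")
    rows <- rows[!drop, ]
  }
  surface_from_rows(rows, fixture, target)
}

# Long rows (cell_id, date, predicted) -> dense cells x days matrix.
surface_from_rows <- function(rows, fixture, target) {
  dates <- sort(unique(rows$date))
  ci <- match(rows$cell_id, fixture$grid$cell_id)
  di <- match(rows$date, dates)
  values <- matrix(NA_real_, nrow(fixture$grid), length(dates))
  values[cbind(ci, di)] <- rows$predicted
  structure(list(values = values, cell_id = fixture$grid$cell_id,
                 dates = dates, target = target),
            class = "exposure_surface")
}

#' @export
print.exposure_surface <- function(x, ...) {
  cat("<exposure_surface> target ", x$target, ", ", nrow(x$values),
      " cells x ", length(x$dates), " days, mean ",
      round(mean(x$values, na.rm = TRUE), 1), " ug/m3\n", sep = "")
  invisible(x)
}

# Restrict a surface to one calendar year, requiring full coverage of the
# days present for that year.
surface_year <- function(surface, year) {
  di <- which(year_of(surface$dates) == year)
  if (length(di) == 0) stop("surface has no days in year ", year)
  list(values = surface$values[, di, drop = FALSE],
       dates = surface$dates[di])
}
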