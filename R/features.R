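# Frozen predictor column order: the 14 predictors of the exposure model.
# x/y stand in for longitude/latitude (projected meters), date_index for the
# integer date, idw_baseline is both a predictor and the additive baseline.
.feature_cols <- c("x", "y", "date_index", "idw_baseline",
                   "aod_terra", "aod_aqua", "modeled_pm", "temperature",
                   "precipitation", "vapor_pressure", "pbl_height",
                   "wind_u", "wind_v", "road_density")

#' Frozen feature-column order
#'
#' The 14 predictor columns of the exposure model, in the order used by the
#' feature tables and the trained boosters.
#' @return Character vector of length 14.
#' @export
feature_columns <- function() .feature_cols

#' Inverse-distance-weighted interpolation
#'
#' Classic IDW: each target value is the weighted mean of source values with
#' weights `d^-exponent` on planar Euclidean distance.  A target closer than
#' `eps` (default 1 m) to a source returns that source's value exactly, so a
#' station colocated with a grid centroid reproduces its own observation.
#' The output is a convex combination and therefore bounded by the source
#' range.
#'
#' @param tx,ty target coordinates (projected meters).
#' @param sx,sy,values source coordinates and values; sources must be
#'   non-empty.
#' @param exponent positive distance exponent (default 2).
#' @param eps coincidence cutoff in meters.
#' @return Numeric vector of interpolated values, one per target.
#' @examples
#' idw_interpolate(0, 0, c(1, 2), c(0, 0), c(10, 40))  # 16
#' @export
idw_interpolate <- function(tx, ty, sx, sy, values, exponent = 2, eps = 1) {
  if (length(sx) == 0) stop("no same-day observations: empty IDW source set")
  stopifnot(exponent > 0, length(sx) == length(sy),
            length(sx) == length(values))
  .idw_core(tx, ty, sx, sy, values, exponent, eps, exclude = NULL)
}

# Shared IDW kernel with optional per-target source exclusion
# (`exclude`: logical targets x sources matrix).
.idw_core <- function(tx, ty, sx, sy, values, exponent, eps, exclude = NULL) {
  d <- sqrt(outer(tx, sx, "-")^2 + outer(ty, sy, "-")^2)
  usable <- if (is.null(exclude)) {
    matrix(TRUE, length(tx), length(sx))
  } else {
    !exclude
  }
  out <- rep(NA_real_, length(tx))
  coin <- d < eps & usable
  has_coin <- rowSums(coin) > 0
  if (any(has_coin)) {
    first <- apply(coin[has_coin, , drop = FALSE], 1, which.max)
    out[has_coin] <- values[first]
  }
  rest <- which(!has_coin)
  if (length(rest)) {
    w <- d[rest, , drop = FALSE]^(-exponent)
    w[!usable[rest, , drop = FALSE]] <- 0  # before weighting: an excluded
    # source at distance 0 would otherwise give Inf * 0 = NaN
    tot <- rowSums(w)
    # normalise before the weighted sum so a single usable source returns
    # its value exactly
    out[rest] <- ifelse(tot > 0, as.vector((w / tot) %*% values), NA_real_)
  }
  out
}

# IDW baselines for arbitrary rows from a station-day source table,
# grouped by date.  `rows` needs x, y, date (and station_id when
# exclude_self); `sources` needs station_id, x, y, date, value.  Rows on
# days with no usable source get NA.
idw_from_station_days <- function(rows, sources, exponent = 2, eps = 1,
                                  exclude_self = FALSE) {
  out <- rep(NA_real_, nrow(rows))
  for (d in unique(rows$date)) {
    ri <- which(rows$date == d)
    si <- which(sources$date == d)
    if (length(si) == 0) next
    excl <- NULL
    if (exclude_self) {
      excl <- outer(rows$station_id[ri], sources$station_id[si], "==")
    }
    out[ri] <- .idw_core(rows$x[ri], rows$y[ri],
                         sources$x[si], sources$y[si], sources$value[si],
                         exponent, eps, exclude = excl)
  }
  out
}

# Station-day table -> IDW source table for one target kind.
station_day_sources <- function(fixture, station_days,
                                target = c("mean", "max")) {
  target <- match.arg(target)
  col <- if (target == "mean") "mean_pm25" else "max_pm25"
  s <- dplyr::left_join(station_days, fixture$stations,
                        by = "station_id")
  tibble::tibble(station_id = s$station_id, x = s$x, y = s$y,
                 date = s$date, value = s[[col]])
}

# Non-IDW predictor block for (cell index, day index) row vectors, applying
# the temporal-aggregation rule: the daily-max target reads modeled PM,
# boundary-layer height and winds at 10:00 instead of the daily mean.
predictor_block <- function(predictors, ci, di, target) {
  at10 <- target == "max"
  pick <- function(day_name, h10_name) {
    m <- predictors[[if (at10) h10_name else day_name]]
    m[cbind(ci, di)]
  }
  tibble::tibble(
    aod_terra = predictors$aod_terra[cbind(ci, di)],
    aod_aqua = predictors$aod_aqua[cbind(ci, di)],
    modeled_pm = pick("modeled_pm", "modeled_pm_10"),
    temperature = (predictors$tmax[cbind(ci, di)] +
                     predictors$tmin[cbind(ci, di)]) / 2 + 273.15,
    precipitation = predictors$precipitation[cbind(ci, di)],
    vapor_pressure = predictors$vapor_pressure[cbind(ci, di)],
    pbl_height = pick("pbl_height", "pbl_height_10"),
    wind_u = pick("wind_u", "wind_u_10"),
    wind_v = pick("wind_v", "wind_v_10"),
    road_density = predictors$road_density[ci]
  )
}

#' Build training feature rows for station-days
#'
#' One row per retained station-day, carrying the 14 predictors and the
#' observed target.  The IDW baseline of a station's own row is always
#' computed from the *other* stations' same-day observations; rows on days
#' with no other observation (undefined baseline) are dropped with a
#' message.
#'
#' @param fixture a [make_region_fixture()] object.
#' @param station_days tibble from [aggregate_station_days()].
#' @param predictors a [simulate_predictors()] object (or any list with the
#'   same layers).
#' @param target `"mean"` or `"max"`: which daily target the rows are for;
#'   controls both the observed column and the 10:00 temporal rule.
#' @param idw_exponent IDW distance exponent.
#' @return Tibble: `station_id`, `date`, `observed`, then the columns of
#'   [feature_columns()].
#' @export
training_features <- function(fixture, station_days, predictors,
                              target = c("mean", "max"), idw_exponent = 2) {
  target <- match.arg(target)
  sources <- station_day_sources(fixture, station_days, target)
  rows <- dplyr::left_join(station_days, fixture$stations, by = "station_id")
  out <- assemble_features(fixture, predictors, target,
                           ids = rows$station_id, cell_id = rows$cell_id,
                           x = rows$x, y = rows$y, date = rows$date,
                           sources = sources, exclude_self = TRUE,
                           exponent = idw_exponent)
  out <- tibble::add_column(out,
                            observed = sources$value[match(
                              paste(out$station_id, out$date),
                              paste(sources$station_id, sources$date))],
                            .after = "date")
  out
}

#' Build prediction feature rows for grid cells
#'
#' One row per in-region cell and requested day, with the IDW baseline
#' interpolated from all stations observing that day.  Days with no
#' observation at all have an undefined baseline; their rows are dropped
#' with a message.
#'
#' @inheritParams training_features
#' @param dates days to predict (default: all fixture dates).
#' @return Tibble: `cell_id`, `date`, then [feature_columns()].
#' @export
prediction_features <- function(fixture, station_days, predictors,
                                target = c("mean", "max"),
                                dates = NULL, idw_exponent = 2) {
  target <- match.arg(target)
  dates <- dates %||% predictors$dates
  sources <- station_day_sources(fixture, station_days, target)
  nc <- nrow(fixture$grid)
  out <- assemble_features(
    fixture, predictors, target,
    ids = NULL, cell_id = rep(fixture$grid$cell_id, length(dates)),
    x = rep(fixture$grid$x, length(dates)),
    y = rep(fixture$grid$y, length(dates)),
    date = rep(dates, each = nc),
    sources = sources, exclude_self = FALSE, exponent = idw_exponent)
  out
}

# Shared assembly: IDW baseline + predictor block + metadata, frozen order.
assemble_features <- function(fixture, predictors, target, ids, cell_id,
                              x, y, date, sources, exclude_self, exponent) {
  ci <- match(cell_id, predictors$cell_id)
  di <- match(date, predictors$dates)
  if (anyNA(ci) || anyNA(di)) {
    stop("predictor rasters do not cover every requested cell-day")
  }
  rows <- tibble::tibble(station_id = ids %||% NA_character_,
                         x = x, y = y, date = date)
  idw <- idw_from_station_days(rows, sources, exponent = exponent,
                               exclude_self = exclude_self)
  block <- predictor_block(predictors, ci, di, target)
  out <- tibble::tibble(
    station_id = rows$station_id, cell_id = cell_id, date = date,
    x = x, y = y,
    date_index = as.integer(date - min(predictors$dates)),
    idw_baseline = idw)
  out <- dplyr::bind_cols(out, block)
  drop <- !is.finite(out$idw_baseline)
  if (any(drop)) {
    message(sum(drop), " row(s) dropped: no same-day observations ",
            "to define the IDW baseline")
    out <- out[!drop, ]
  }
  if (is.null(ids)) out$station_id <- NULL
  out
}

#' Extract the model matrix from a feature table
#'
#' @param features a tibble from [training_features()] or
#'   [prediction_features()].
#' @return Numeric matrix with the columns of [feature_columns()], in order.
#' @export
feature_matrix <- function(features) {
  missing <- setdiff(.feature_cols, names(features))
  if (length(missing)) {
    stop("feature table lacks columns: ", paste(missing, collapse = ", "))
  }
  as.matrix(features[, .feature_cols])
}
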