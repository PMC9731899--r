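#' Regulatory annual mean: mean of four quarterly means
#'
#' The regulatory "yearly" mean is the mean of four 3-month means
#' (quarterly mean = mean of that quarter's daily values), per the Mexican
#' annual PM2.5 standard.  Quarters are calendar quarters (Jan-Mar,
#' Apr-Jun, Jul-Sep, Oct-Dec).  On unbalanced data this deliberately
#' differs from the plain mean of all days; the two agree when every
#' quarter contributes the same number of days.
#'
#' @param values numeric vector (one cell's daily series) or cells x days
#'   matrix of daily means (ug/m^3).
#' @param dates `Date` vector, one per value/column, all within one
#'   calendar year.
#' @return Numeric scalar (or per-row vector).  `NA` with a message when a
#'   quarter has no value.
#' @examples
#' d <- seq(as.Date("2012-01-01"), as.Date("2012-12-31"), by = "day")
#' regulatory_annual_mean(rep(12, length(d)), d)  # 12
#' @export
regulatory_annual_mean <- function(values, dates) {
  m <- if (is.matrix(values)) values else matrix(values, nrow = 1)
  stopifnot(ncol(m) == length(dates))
  if (length(unique(year_of(dates))) != 1) {
    stop("series must cover exactly one calendar year")
  }
  q <- (month_of(dates) - 1L) %/% 3L + 1L
  if (length(unique(q)) < 4) {
    message("empty quarter(s): regulatory annual mean undefined")
    out <- rep(NA_real_, nrow(m))
  } else {
    qmeans <- vapply(1:4, function(k) rowMeans(m[, q == k, drop = FALSE]),
                     numeric(nrow(m)))
    out <- rowMeans(matrix(qmeans, nrow = nrow(m)))
  }
  if (!is.matrix(values)) out[1] else out
}

# Per-cell regulatory annual means for one calendar year of a daily-mean
# surface.
annual_surface <- function(surface, year) {
  sy <- surface_year(surface, year)
  regulatory_annual_mean(sy$values, sy$dates)
}

#' Area-weighted cell populations from a density raster
#'
#' Per model cell, the population density is the area-weighted mean of the
#' densities of the intersecting raster cells (the raster grid is in
#' general offset from the model grid); persons per cell are density times
#' cell area.  Both grids are axis-aligned, so intersection areas are
#' products of interval overlaps and the computation is exact.
#'
#' @param fixture a [make_region_fixture()] object.
#' @param raster population raster (list `x0`, `y0`, `dx`, `dy`, `nx`,
#'   `ny`, `density` matrix in persons/km^2); defaults to the fixture's.
#' @return Tibble: `cell_id`, `density` (persons/km^2), `persons`.
#' @export
populate_cells <- function(fixture, raster = fixture$population) {
  g <- fixture$grid
  half <- fixture$cell_size / 2
  xe <- raster$x0 + (0:raster$nx) * raster$dx
  ye <- raster$y0 + (0:raster$ny) * raster$dy
  density <- vapply(seq_len(nrow(g)), function(i) {
    xlo <- g$x[i] - half
    xhi <- g$x[i] + half
    ylo <- g$y[i] - half
    yhi <- g$y[i] + half
    ix <- which(xe[-1] > xlo & xe[-length(xe)] < xhi)
    iy <- which(ye[-1] > ylo & ye[-length(ye)] < yhi)
    if (length(ix) == 0 || length(iy) == 0 ||
        xe[min(ix)] > xlo || xe[max(ix) + 1] < xhi ||
        ye[min(iy)] > ylo || ye[max(iy) + 1] < yhi) {
      stop("population raster does not cover model cell ", g$cell_id[i])
    }
    wx <- pmin(xe[ix + 1], xhi) - pmax(xe[ix], xlo)
    wy <- pmin(ye[iy + 1], yhi) - pmax(ye[iy], ylo)
    w <- outer(wx, wy)
    sum(w * raster$density[ix, iy, drop = FALSE]) / sum(w)
  }, numeric(1))
  tibble::tibble(cell_id = g$cell_id, density = density,
                 persons = density * (fixture$cell_size / 1000)^2)
}

#' Regulatory-compliance report with population weighting
#'
#' Compares a daily-mean exposure surface against the annual and daily
#' permissible limits (defaults 10 and 41 ug/m^3): the persons (count and
#' fraction) whose regulatory annual mean is worse than the annual limit
#' and worse than twice it; the mean number of exceedance days per person
#' (population-weighted, with the unweighted variant alongside); and total
#' person-days of exceedance, `sum over cells of persons x days above the
#' daily limit`.  Exceedance is strict (`>`), i.e. "worse than" the limit.
#'
#' @param surface a daily-mean `exposure_surface`.
#' @param populations tibble from [populate_cells()].
#' @param limits list/vector with `annual` and `daily` limits (ug/m^3).
#' @param year calendar year to report (default: first year in the
#'   surface).
#' @param comparison optional second surface (e.g. [idw_surface()]);
#'   reported under `$comparison` with the same fields.
#' @return List of class `compliance_report`.
#' @export
compliance_report <- function(surface, populations,
                              limits = c(annual = 10, daily = 41),
                              year = NULL, comparison = NULL) {
  stopifnot(surface$target == "mean")
  limits <- as.list(limits)
  stopifnot(limits$annual > 0, limits$daily > 0)
  year <- year %||% min(year_of(surface$dates))
  sy <- surface_year(surface, year)
  persons <- populations$persons[match(surface$cell_id,
                                       populations$cell_id)]
  stopifnot(all(is.finite(persons)))
  ann <- annual_surface(surface, year)
  exceed_days <- rowSums(sy$values > limits$daily)
  total <- sum(persons)
  out <- list(
    year = year,
    limits = limits,
    persons_total = total,
    persons_above_annual = sum(persons[which(ann > limits$annual)]),
    frac_above_annual = sum(persons[which(ann > limits$annual)]) / total,
    frac_above_twice_annual =
      sum(persons[which(ann > 2 * limits$annual)]) / total,
    mean_exceedance_days = sum(persons * exceed_days) / total,
    mean_exceedance_days_unweighted = mean(exceed_days),
    person_days = sum(persons * exceed_days)
  )
  if (!is.null(comparison)) {
    out$comparison <- compliance_report(comparison, populations, limits,
                                        year = year)
  }
  structure(out, class = "compliance_report")
}

#' @export
print.compliance_report <- function(x, ...) {
  cat("<compliance_report> year ", x$year, ": ",
      round(100 * x$frac_above_annual, 1), "% of ",
      format(round(x$persons_total), big.mark = ","),
      " persons above the annual limit (",
      round(100 * x$frac_above_twice_annual, 1), "% above twice it); ",
      round(x$mean_exceedance_days, 1),
      " exceedance days/person; ",
      format(round(x$person_days), big.mark = ","), " person-days\n",
      sep = "")
  if (!is.null(x$comparison)) {
    cat("  IDW-only comparison: ",
        round(x$comparison$mean_exceedance_days, 1), " days/person, ",
        format(round(x$comparison$person_days), big.mark = ","),
        " person-days\n", sep = "")
  }
  invisible(x)
}

#' Population-weighted ECDF of annual exposure
#'
#' The empirical cumulative distribution of per-cell regulatory annual
#' means, weighted by cell population: the fraction of persons whose
#' cell's annual mean is at or below each concentration.  Right-continuous,
#' nondecreasing, 0 to 1.
#'
#' @inheritParams compliance_report
#' @param year calendar year.
#' @return Tibble of class `population_ecdf`: `concentration` (sorted),
#'   `cum_fraction`.
#' @export
population_ecdf <- function(surface, populations, year = NULL) {
  year <- year %||% min(year_of(surface$dates))
  ann <- annual_surface(surface, year)
  persons <- populations$persons[match(surface$cell_id,
                                       populations$cell_id)]
  o <- order(ann)
  out <- tibble::tibble(concentration = ann[o],
                        cum_fraction = cumsum(persons[o]) / sum(persons))
  class(out) <- c("population_ecdf", class(out))
  out
}

#' Quantile of a population ECDF
#'
#' Smallest concentration at which the cumulative population fraction
#' reaches `p` (e.g. `p = 0.1`: the concentration below which 10% of the
#' population falls).
#'
#' @param ecdf a [population_ecdf()] tibble.
#' @param p probabilities in `[0, 1]`.
#' @return Concentrations, one per `p`.
#' @export
ecdf_quantile <- function(ecdf, p) {
  vapply(p, function(pp) {
    ecdf$concentration[which(ecdf$cum_fraction >= pp - 1e-12)[1]]
  }, numeric(1))
}

#' Daily max:mean ratio series with a rain split
#'
#' Per day, the ratio of the spatial mean of the daily-max surface to the
#' spatial mean of the daily-mean surface ("collapsing across all cells" by
#' averaging the surfaces first; `per_cell_ratio = TRUE` instead averages
#' per-cell ratios).  Days are labelled rainy when the mean per-cell
#' precipitation reaches `rain_threshold` (default 1 mm), and group means
#' of the ratio are reported for rainy and non-rainy days, optionally
#' restricted to one season.
#'
#' @param mean_surface,max_surface aligned `exposure_surface` objects.
#' @param precipitation cells x days matrix (mm) aligned with the
#'   surfaces' dates (e.g. the `precipitation` layer of
#'   [simulate_predictors()]), plus its `dates`.
#' @param precip_dates dates of the precipitation columns.
#' @param rain_threshold mm.
#' @param season_filter optional season label; group means are computed on
#'   that season's days only (the headline analysis uses `"rainy"`).
#' @param per_cell_ratio alternative collapsing rule (mean of per-cell
#'   ratios).
#' @return List: `days` (tibble `date`, `ratio`, `mean_precip`, `rainy`,
#'   `season`) and `group_means` (tibble `rainy`, `n_days`, `mean_ratio`).
#' @export
daily_ratio_series <- function(mean_surface, max_surface, precipitation,
                               precip_dates, rain_threshold = 1,
                               season_filter = NULL,
                               per_cell_ratio = FALSE) {
  stopifnot(identical(mean_surface$cell_id, max_surface$cell_id))
  dates <- as.Date(intersect(intersect(mean_surface$dates,
                                       max_surface$dates),
                             precip_dates),
                   origin = "1970-01-01")
  i1 <- match(dates, mean_surface$dates)
  i2 <- match(dates, max_surface$dates)
  i3 <- match(dates, precip_dates)
  denom <- colMeans(mean_surface$values[, i1, drop = FALSE])
  if (per_cell_ratio) {
    ratio <- colMeans(max_surface$values[, i2, drop = FALSE] /
                        mean_surface$values[, i1, drop = FALSE])
  } else {
    ratio <- colMeans(max_surface$values[, i2, drop = FALSE]) / denom
  }
  ok <- denom > 0
  if (any(!ok)) {
    message(sum(!ok), " day(s) excluded: zero spatial mean")
  }
  days <- tibble::tibble(
    date = dates[ok], ratio = ratio[ok],
    mean_precip = colMeans(precipitation[, i3, drop = FALSE])[ok],
    season = assign_season(dates[ok]))
  days$rainy <- days$mean_precip >= rain_threshold
  sel <- if (is.null(season_filter)) days else
    days[days$season == season_filter, ]
  group_means <- sel |>
    dplyr::group_by(.data$rainy) |>
    dplyr::summarise(n_days = dplyr::n(), mean_ratio = mean(.data$ratio),
                     .groups = "drop")
  list(days = days, group_means = group_means)
}

#' Heat and PM2.5 co-occurrence summary
#'
#' Relates the daily-mean PM2.5 surface to a daily-mean temperature
#' surface over all cell-days: the overall Kendall tau-b; per-season PM
#' quartiles conditional on temperature binned to 0.1 degC (the heatmap
#' summaries); the median temperature on cell-days exceeding the daily PM
#' limit versus all others; and the median PM on cell-days at or above the
#' temperature threshold versus all others.
#'
#' @param pm_surface daily-mean `exposure_surface`.
#' @param temperature cells x days matrix of daily mean temperature (degC)
#'   aligned with `pm_surface$dates` (e.g. `(tmax + tmin) / 2` of the
#'   predictor set, or the truth field's temperature).
#' @param daily_limit PM2.5 daily limit (ug/m^3, default 41).
#' @param temp_threshold temperature cut (degC, default 20).
#' @return List: `tau`, `n_cell_days`, `n_exceedance`,
#'   `median_temp_exceedance`, `median_temp_other`, `n_hot`,
#'   `median_pm_hot`, `median_pm_other`, and `conditional_quartiles`
#'   (tibble `season`, `temp_bin`, `n`, `q25`, `q50`, `q75`).
#' @export
heat_cooccurrence <- function(pm_surface, temperature, daily_limit = 41,
                              temp_threshold = 20) {
  pm <- as.vector(pm_surface$values)
  tmp <- as.vector(temperature)
  stopifnot(length(pm) == length(tmp))
  season <- rep(assign_season(pm_surface$dates), each = nrow(pm_surface$values))
  exceed <- pm > daily_limit
  hot <- tmp >= temp_threshold
  cq <- tibble::tibble(season = season, temp_bin = round(tmp, 1), pm = pm) |>
    dplyr::group_by(.data$season, .data$temp_bin) |>
    dplyr::summarise(n = dplyr::n(),
                     q25 = quantile(.data$pm, 0.25, names = FALSE),
                     q50 = median(.data$pm),
                     q75 = quantile(.data$pm, 0.75, names = FALSE),
                     .groups = "drop")
  list(
    tau = kendall_tau(pm, tmp),
    n_cell_days = length(pm),
    n_exceedance = sum(exceed),
    median_temp_exceedance = if (any(exceed)) median(tmp[exceed]) else NA_real_,
    median_temp_other = if (any(!exceed)) median(tmp[!exceed]) else NA_real_,
    n_hot = sum(hot),
    median_pm_hot = if (any(hot)) median(pm[hot]) else NA_real_,
    median_pm_other = if (any(!hot)) median(pm[!hot]) else NA_real_,
    conditional_quartiles = cq
  )
}

#' Point-in-polygon test (boundary-inclusive)
#'
#' Even-odd ray-casting with an explicit on-edge check: points on the
#' polygon boundary count as inside, making centroid assignment
#' deterministic.
#'
#' @param px,py point coordinates.
#' @param xy polygon vertex matrix (2 columns, not closed).
#' @param eps on-edge tolerance in coordinate units.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, xy, eps = 1e-6) {
  n <- nrow(xy)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]
    xj <- xy[j, 1]; yj <- xy[j, 2]
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx^2 + dy^2
    t <- if (len2 > 0) pmin(pmax(((px - xi) * dx + (py - yi) * dy) / len2,
                                 0), 1) else 0
    d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
    on_edge <- on_edge | d2 <= eps^2
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside | on_edge
}

#' Link exposure to scored areal units
#'
#' Each polygon unit is assigned the unweighted mean of the annual mean
#' predictions of the cells whose centroids fall inside it (boundary
#' centroids count as inside).  Units containing no centroid are reported
#' missing and excluded from the correlation.  Also reports the Kendall
#' tau-b between the units' marginalization scores and their exposure, and
#' mean exposure within 0.5-unit score bins (`[-2, -1.5)`, `[-1.5, -1)`,
#' ...).
#'
#' The annual value is the plain calendar-year mean of the daily
#' predictions (the deprivation linkage summarises predictions, not
#' regulatory compliance).
#'
#' @param surface daily-mean `exposure_surface`.
#' @param fixture a [make_region_fixture()] object (provides cell centroids
#'   and, by default, the polygons).
#' @param year calendar year (default: first in the surface).
#' @param polygons list of polygon units (default `fixture$polygons`).
#' @return List: `units` (tibble `unit_id`, `marginalization`, `n_cells`,
#'   `exposure`), `tau`, `bins` (tibble `bin_low`, `bin_high`, `n_units`,
#'   `mean_exposure`).
#' @export
areal_link <- function(surface, fixture, year = NULL,
                       polygons = fixture$polygons) {
  year <- year %||% min(year_of(surface$dates))
  sy <- surface_year(surface, year)
  ann <- rowMeans(sy$values)
  cx <- fixture$grid$x[match(surface$cell_id, fixture$grid$cell_id)]
  cy <- fixture$grid$y[match(surface$cell_id, fixture$grid$cell_id)]
  units <- dplyr::bind_rows(lapply(polygons, function(pg) {
    inside <- point_in_polygon(cx, cy, pg$xy)
    tibble::tibble(unit_id = pg$unit_id,
                   marginalization = pg$marginalization,
                   n_cells = sum(inside),
                   exposure = if (any(inside)) mean(ann[inside]) else NA_real_)
  }))
  ok <- units[!is.na(units$exposure), ]
  tau <- if (nrow(ok) >= 2) {
    kendall_tau(ok$marginalization, ok$exposure)
  } else {
    NA_real_
  }
  bins <- ok |>
    dplyr::mutate(bin_low = floor(.data$marginalization / 0.5) * 0.5) |>
    dplyr::group_by(.data$bin_low) |>
    dplyr::summarise(n_units = dplyr::n(),
                     mean_exposure = mean(.data$exposure),
                     .groups = "drop") |>
    dplyr::mutate(bin_high = .data$bin_low + 0.5) |>
    dplyr::relocate("bin_low", "bin_high")
  list(units = units, tau = tau, bins = bins)
}
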