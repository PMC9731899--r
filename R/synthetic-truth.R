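#' Generate the latent truth field for a fixture
#'
#' Simulates what the real atmosphere supplies and the analysis never
#' observes directly: a strictly positive daily-mean PM2.5 surface per
#' cell-day, a unit-mean 24-hour multiplier profile per day whose modal peak
#' sits at a configurable hour (default 10, mid-morning), daily mean
#' temperature and precipitation fields, and a season label per day.
#'
#' Structure emulated: two dry seasons with higher concentrations and a
#' rainy season with lower ones; day-to-day autocorrelated regional
#' anomalies; a smooth time-constant spatial field; a positive coupling
#' between a day's temperature anomaly and its PM2.5 (hotter-than-usual
#' days carry more particulate matter); and mild washout on days with at
#' least `1 mm` regional precipitation.
#'
#' @param fixture a [make_region_fixture()] object.
#' @param peak_hour hour (0-23) at which the diurnal profile peaks.
#' @param spatial_sd sd (log scale) of the smooth spatial field.
#' @param spatial_range range of the spatial field, in multiples of the cell
#'   side (the generator's spatial-covariance knob; real residual covariance
#'   is unknown and this smooth-field form is an assumption).
#' @param temperature_coupling increase in log PM2.5 per 1-sd positive
#'   temperature anomaly; set negative to plant an inverted dependence or 0
#'   for independence.
#' @param rain_washout decrease in log PM2.5 on days whose regional
#'   precipitation reaches 1 mm.
#' @param dry_season_wet_prob probability of a wet day outside the rainy
#'   season (set to 0 to confine precipitation to the rainy season).
#' @param seasonal_temperature if `FALSE`, the seasonal temperature cycle is
#'   flattened (one mean for all seasons).  With `temperature_coupling = 0`
#'   this makes temperature fully independent of PM2.5 — the calendar
#'   otherwise links the two through their shared seasonal cycles — which is
#'   the configuration null-calibration checks need.
#' @param temperature_spatial_sd sd (degC) of the smooth static spatial
#'   temperature field.  Set to 0 (with the seasonal cycle flattened) for
#'   calibration runs: two independent smooth static fields align by chance,
#'   so a spatially structured temperature inflates the replicate spread of
#'   any PM-temperature correlation even under independence.
#' @param seed integer seed.
#' @return Object of class `truth_field`: list with `mean` (cells x days
#'   matrix, ug/m^3), `profile` (24 x days, unit column means), `season`
#'   (per day), `temperature` (cells x days, degC daily mean),
#'   `precipitation` (cells x days, mm), `dates`, `cell_id`, `peak_hour`.
#' @export
make_truth_field <- function(fixture, peak_hour = 10, spatial_sd = 0.35,
                             spatial_range = 3, temperature_coupling = 0.15,
                             rain_washout = 0.15, dry_season_wet_prob = 0.04,
                             seasonal_temperature = TRUE,
                             temperature_spatial_sd = 1.5, seed = 1) {
  stopifnot(inherits(fixture, "region_fixture"),
            peak_hour %in% 0:23, spatial_sd >= 0)
  with_seed(seed, {
    dates <- fixture$dates
    nd <- length(dates)
    ncell <- nrow(fixture$grid)
    season <- assign_season(dates)

    season_level <- c(cold_dry = 32, warm_dry = 27, rainy = 17)
    season_temp <- if (seasonal_temperature) {
      c(cold_dry = 13, warm_dry = 21, rainy = 17)
    } else {
      c(cold_dry = 17, warm_dry = 17, rainy = 17)
    }

    ar1 <- function(n, phi, sd_innov) {
      z <- numeric(n)
      z[1] <- rnorm(1, 0, sd_innov / sqrt(1 - phi^2))
      for (i in seq_len(n - 1)) z[i + 1] <- phi * z[i] + rnorm(1, 0, sd_innov)
      z
    }
    day_anom <- ar1(nd, 0.6, 0.25 * sqrt(1 - 0.6^2))   # log scale, sd ~0.25
    temp_anom <- ar1(nd, 0.7, 2.5 * sqrt(1 - 0.7^2))   # degC, sd ~2.5

    # Precipitation: wet days mostly in the rainy season, Gamma amounts,
    # with a smooth spatial modulation.
    wet_p <- ifelse(season == "rainy", 0.65, dry_season_wet_prob)
    wet <- rbinom(nd, 1, wet_p) == 1
    day_precip <- ifelse(wet, rgamma(nd, shape = 1.2, scale = 5), 0)
    precip_space <- exp(0.5 * gauss_smooth_field(
      fixture$grid$x, fixture$grid$y, spatial_range * fixture$cell_size))
    precipitation <- outer(precip_space, day_precip)

    spatial <- spatial_sd * gauss_smooth_field(
      fixture$grid$x, fixture$grid$y, spatial_range * fixture$cell_size)
    temp_space <- temperature_spatial_sd * gauss_smooth_field(
      fixture$grid$x, fixture$grid$y, spatial_range * fixture$cell_size)

    log_day <- log(season_level[season]) + day_anom +
      temperature_coupling * (temp_anom / 2.5) -
      rain_washout * (day_precip >= 1)
    resid <- matrix(rnorm(ncell * nd, 0, 0.12), ncell, nd)
    mean_pm <- exp(outer(spatial, log_day, "+") + resid)

    temperature <- outer(temp_space, season_temp[season] + temp_anom, "+") +
      matrix(rnorm(ncell * nd, 0, 0.5), ncell, nd)

    # Diurnal multiplier: Gaussian bump at peak_hour, day-jittered
    # amplitude, normalised to unit mean so daily means are preserved.
    h <- 0:23
    amp <- 1.3 * exp(rnorm(nd, 0, 0.15))
    shape <- 1 + outer(exp(-0.5 * ((h - peak_hour) / 2.5)^2), amp)
    profile <- sweep(shape, 2, colMeans(shape), "/")

    structure(
      list(mean = mean_pm, profile = profile, season = season,
           temperature = temperature, precipitation = precipitation,
           dates = dates, cell_id = fixture$grid$cell_id,
           peak_hour = as.integer(peak_hour)),
      class = "truth_field"
    )
  })
}

#' @export
print.truth_field <- function(x, ...) {
  cat("<truth_field> ", nrow(x$mean), " cells x ", ncol(x$mean),
      " days, peak hour ", x$peak_hour, ", mean PM2.5 ",
      round(mean(x$mean), 1), " ug/m3\n", sep = "")
  invisible(x)
}
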