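#' Simulate hourly monitoring-station observations
#'
#' Hourly PM2.5 at a station is the latent daily mean at its host cell,
#' times the day's hourly multiplier, times unit-mean lognormal station
#' noise.  The noise has two components: a station-day factor (`noise_sd`,
#' shared by the day's hours — local sources and calibration drift that
#' displace the whole day) and a smaller independent hourly jitter
#' (`hourly_noise_sd`).  Keeping most of the noise at the day scale
#' matters for the daily 1-h maximum: real maxima ride the shared diurnal
#' peak, whereas an all-hourly-independent noise would make the sampled
#' maximum an unpredictable extreme-value artifact.  Each station-hour is
#' then independently dropped at the missingness rate, so that (at rates
#' above ~0.25) some station-days fall below the 18-hour completeness rule
#' downstream.
#'
#' @param fixture a [make_region_fixture()] object.
#' @param truth a [make_truth_field()] object for the same fixture.
#' @param missingness per-hour drop probability, in `[0, 1)`.
#' @param noise_sd sd (log scale) of the station-day lognormal noise
#'   (default 0.3; multiplicative noise keeps concentrations positive and
#'   right-skewed).
#' @param hourly_noise_sd sd (log scale) of the independent hourly jitter.
#' @param seed integer seed.
#' @return Tibble of hourly records: `station_id`, `date` (UTC-6 civil
#'   day), `hour` (0-23), `pm25` (ug/m^3).
#' @export
simulate_observations <- function(fixture, truth, missingness = 0.1,
                                  noise_sd = 0.3, hourly_noise_sd = 0.15,
                                  seed = 1) {
  stopifnot(inherits(fixture, "region_fixture"),
            inherits(truth, "truth_field"),
            missingness >= 0, missingness < 1, noise_sd >= 0,
            hourly_noise_sd >= 0)
  with_seed(seed, {
    nd <- length(truth$dates)
    out <- lapply(seq_len(nrow(fixture$stations)), function(si) {
      ci <- match(fixture$stations$cell_id[si], truth$cell_id)
      base <- truth$mean[ci, ]                        # per day
      day_noise <- exp(rnorm(nd, 0, noise_sd) - noise_sd^2 / 2)
      noise <- rep(day_noise, each = 24) *
        matrix(exp(rnorm(24 * nd, 0, hourly_noise_sd) -
                     hourly_noise_sd^2 / 2), 24, nd)
      vals <- truth$profile * noise * rep(base, each = 24)
      keep <- matrix(runif(24 * nd) >= missingness, 24, nd)
      tibble::tibble(
        station_id = fixture$stations$station_id[si],
        date = rep(truth$dates, each = 24)[as.vector(keep)],
        hour = rep(0:23, times = nd)[as.vector(keep)],
        pm25 = as.vector(vals)[as.vector(keep)]
      )
    })
    dplyr::bind_rows(out)
  })
}

# Blend a standardised signal with independent standard-normal noise:
# weight 1 returns the signal itself, weight 0 pure noise.
blend <- function(signal_z, w) w * signal_z + (1 - w) * matrix(
  rnorm(length(signal_z)), nrow(as.matrix(signal_z)))

#' Simulate gridded predictor fields
#'
#' Emits the analysis' predictor set per cell-day: two aerosol-optical-depth
#' (AOD) layers with realistic missingness, a modeled surface-PM layer,
#' daily maximum and minimum temperature, precipitation, vapor pressure,
#' boundary-layer height, two wind components, and static road density.
#' Dynamic layers that the daily-max model reads at 10:00 (modeled PM,
#' boundary-layer height, winds) are emitted twice: as the daily mean and as
#' the 10:00 value.
#'
#' Each dynamic layer is a monotone transform of the latent truth blended
#' with independent noise: with `informativeness = 1` the AOD layers are
#' strictly monotone functions of the truth mean; with `informativeness = 0`
#' they are pure noise.
#'
#' @param fixture,truth as in [simulate_observations()].
#' @param informativeness signal weight in `[0, 1]`.
#' @param aod_day_missing probability that a day has AOD gaps at all.
#' @param aod_cell_missing within an affected day, probability a cell's AOD
#'   is missing.
#' @param seed integer seed.
#' @return Object of class `predictor_set`: list of cells x days matrices
#'   (`aod_terra`, `aod_aqua`, `modeled_pm`, `modeled_pm_10`, `tmax`,
#'   `tmin`, `precipitation`, `vapor_pressure`, `pbl_height`,
#'   `pbl_height_10`, `wind_u`, `wind_u_10`, `wind_v`, `wind_v_10`), a
#'   static `road_density` vector (m/km^2), plus `dates` and `cell_id`.
#' @export
simulate_predictors <- function(fixture, truth, informativeness = 0.8,
                                aod_day_missing = 0.4, aod_cell_missing = 0.5,
                                seed = 1) {
  stopifnot(inherits(fixture, "region_fixture"),
            inherits(truth, "truth_field"),
            informativeness >= 0, informativeness <= 1)
  with_seed(seed, {
    w <- informativeness
    nd <- length(truth$dates)
    ncell <- nrow(truth$mean)
    zpm <- zscore(log(truth$mean))
    # truth at 10:00: daily mean times that day's hour-10 multiplier
    z10 <- zscore(log(sweep(truth$mean, 2, truth$profile[11, ], "*")))
    ztemp <- zscore(truth$temperature)

    add_aod_gaps <- function(m) {
      gap_day <- runif(nd) < aod_day_missing
      gaps <- matrix(FALSE, ncell, nd)
      gaps[, gap_day] <- matrix(runif(ncell * sum(gap_day)) < aod_cell_missing,
                                ncell, sum(gap_day))
      m[gaps] <- NA_real_
      m
    }

    tmean_meas <- mean(truth$temperature) + sd(truth$temperature) *
      blend(ztemp, w)
    # Saturation vapor pressure (Magnus form, Pa) at measured temperature,
    # damped by a fixed mean relative humidity.
    vp_signal <- 0.6 * 610.8 * exp(17.27 * tmean_meas / (tmean_meas + 237.3))

    p <- list(
      aod_terra = add_aod_gaps(exp(-1.1 + 0.45 * blend(zpm, w))),
      aod_aqua = add_aod_gaps(exp(-1.25 + 0.40 * blend(zpm, w))),
      modeled_pm = exp(mean(log(truth$mean)) +
                         sd(log(truth$mean)) * 0.8 * blend(zpm, w)),
      modeled_pm_10 = exp(mean(log(truth$mean)) +
                            sd(log(truth$mean)) * 0.8 * blend(z10, w)),
      tmax = tmean_meas + 5 + matrix(rnorm(ncell * nd, 0, 0.5), ncell, nd),
      tmin = tmean_meas - 5 + matrix(rnorm(ncell * nd, 0, 0.5), ncell, nd),
      precipitation = truth$precipitation *
        exp(matrix(rnorm(ncell * nd, 0, (1 - w) * 0.3), ncell, nd)),
      vapor_pressure = vp_signal *
        exp(matrix(rnorm(ncell * nd, 0, (1 - w) * 0.2), ncell, nd)),
      # Boundary layer and winds anti-correlate with PM: shallow stable
      # layers trap particles.
      pbl_height = exp(log(1200) + 0.4 * blend(-zpm, w)),
      pbl_height_10 = exp(log(850) + 0.4 * blend(-z10, w)),
      wind_u = 1 + 1.5 * blend(-0.3 * zpm, w * 0.5),
      wind_u_10 = 1 + 1.5 * blend(-0.3 * z10, w * 0.5),
      wind_v = 0.5 + 1.5 * blend(-0.3 * zpm, w * 0.5),
      wind_v_10 = 0.5 + 1.5 * blend(-0.3 * z10, w * 0.5)
    )
    # Static road density follows the time-constant spatial PM component.
    zroad <- zscore(rowMeans(log(truth$mean)))
    p$road_density <- as.vector(exp(7.3 + 0.5 * (w * zroad +
                                                   (1 - w) * rnorm(ncell))))
    structure(c(p, list(dates = truth$dates, cell_id = truth$cell_id)),
              class = "predictor_set")
  })
}

#' @export
print.predictor_set <- function(x, ...) {
  cat("<predictor_set> ", length(x$cell_id), " cells x ", length(x$dates),
      " days, layers: ",
      paste(setdiff(names(x), c("dates", "cell_id")), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
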