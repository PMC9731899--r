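test_that("region mask keeps the largest edge-connected low component", {
  # no cell excluded
  e <- matrix(2250, 6, 6)
  expect_identical(region_mask(e, 3000), 1:36)

  # two qualifying components (sizes 5 and 3) split by a high ridge:
  # the larger one wins, diagonal contact does not connect
  e <- matrix(5000, 4, 4)
  e[1, 1:4] <- 2000          # ids 1:4
  e[2, 1] <- 2000            # id 5 -> component {1,2,3,4,5}
  e[3, 2:4] <- 2000          # ids 10,11,12 -> component of 3
  expect_identical(region_mask(e, 3000), c(1:5))

  # empty result when nothing qualifies
  expect_length(region_mask(matrix(4000, 3, 3), 3000), 0)

  # random grids match an independent graph-components oracle
  for (s in 1:5) {
    e <- withr::with_seed(s, matrix(runif(400, 2000, 4000), 20, 20))
    expect_identical(region_mask(e, 3000),
                     oracle_largest_component(e, 3000))
  }
})

test_that("fixture generation is reproducible and respects its invariants", {
  fx1 <- make_region_fixture(n_row = 8, n_col = 8, n_stations = 3,
                             n_years = 1, seed = 7)
  fx2 <- make_region_fixture(n_row = 8, n_col = 8, n_stations = 3,
                             n_years = 1, seed = 7)
  expect_identical(fx1, fx2)
  expect_gt(fx1$cell_size, 0)
  expect_true(all(fx1$stations$cell_id %in% fx1$grid$cell_id))
  expect_true(all(fx1$population$density >= 0))
  # stations lie inside their host cells
  hi <- match(fx1$stations$cell_id, fx1$grid$cell_id)
  expect_true(all(abs(fx1$stations$x - fx1$grid$x[hi]) <= fx1$cell_size / 2))
  expect_true(all(abs(fx1$stations$y - fx1$grid$y[hi]) <= fx1$cell_size / 2))
})

test_that("truth field is positive, season-structured, and peaks mid-morning", {
  sim <- small_sim()
  tr <- sim$truth
  expect_true(all(tr$mean > 0))
  expect_identical(unname(apply(tr$profile, 2, which.max)),
                   rep(tr$peak_hour + 1L, ncol(tr$profile)))
  expect_equal(colMeans(tr$profile), rep(1, ncol(tr$profile)))
  rainy <- tr$season == "rainy"
  expect_lt(mean(tr$mean[, rainy]), mean(tr$mean[, !rainy]))
})

test_that("simulated observations honor missingness, noise and seed", {
  sim <- small_sim()
  # no missingness: every station-day has 24 hourly records
  rec0 <- simulate_observations(sim$fixture, sim$truth, missingness = 0,
                                seed = 31)
  counts <- dplyr::count(rec0, station_id, date)
  expect_true(all(counts$n == 24))

  # noiseless: per-station daily mean equals the truth mean at the host cell
  recq <- simulate_observations(sim$fixture, sim$truth, missingness = 0,
                                noise_sd = 0, hourly_noise_sd = 0, seed = 32)
  agg <- aggregate_station_days(recq)
  ci <- match(sim$fixture$stations$cell_id[
    match(agg$station_id, sim$fixture$stations$station_id)],
    sim$truth$cell_id)
  di <- match(agg$date, sim$truth$dates)
  expect_equal(agg$mean_pm25, sim$truth$mean[cbind(ci, di)])

  # determinism
  expect_identical(simulate_observations(sim$fixture, sim$truth, seed = 33),
                   simulate_observations(sim$fixture, sim$truth, seed = 33))

  # heavy missingness pushes some station-days under 18 retained hours
  rec3 <- simulate_observations(sim$fixture, sim$truth, missingness = 0.3,
                                seed = 34)
  c3 <- dplyr::count(rec3, station_id, date)
  expect_gt(sum(c3$n < 18), 0)
})

test_that("predictor informativeness spans pure signal to pure noise", {
  sim <- small_sim()
  p1 <- simulate_predictors(sim$fixture, sim$truth, informativeness = 1,
                            seed = 41)
  ok <- !is.na(p1$aod_terra)
  # strictly monotone in the truth mean at informativeness 1
  expect_identical(order(p1$aod_terra[ok]), order(sim$truth$mean[ok]))

  p0 <- simulate_predictors(sim$fixture, sim$truth, informativeness = 0,
                            seed = 42)
  ok <- !is.na(p0$aod_terra)
  expect_lt(abs(cor(p0$aod_terra[ok], sim$truth$mean[ok])), 0.02)
  expect_lt(abs(cor(as.vector(p0$modeled_pm), as.vector(sim$truth$mean))),
            0.02)
})

test_that("precipitation can be confined to the rainy season", {
  sim <- small_sim()
  tr <- make_truth_field(sim$fixture, dry_season_wet_prob = 0, seed = 43)
  dry <- tr$season != "rainy"
  expect_true(all(tr$precipitation[, dry] == 0))
  expect_gt(sum(tr$precipitation[, !dry] > 0), 0)
})

test_that("station max:mean ratio behaves like a diurnal cycle", {
  sim <- small_sim()
  agg <- sim$station_days
  expect_true(all(agg$max_pm25 >= agg$mean_pm25))
  # profile is non-constant, so the ratio strictly exceeds 1
  expect_true(all(agg$max_pm25 / agg$mean_pm25 > 1))
  # modal observed peak hour across station-days matches the configured one
  expect_identical(modal_peak_hour(sim$records), sim$truth$peak_hour)
})

test_that("fixture round-trips through plain-text files", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  files <- write_fixture(sim$fixture, records = sim$records, dir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("stations.csv", "grid.csv", "hourly_records.csv",
           "population.csv", "polygons.geojson", "config.yaml")))))
  back <- read_hourly_records(file.path(dir, "hourly_records.csv"))
  expect_equal(nrow(back), nrow(sim$records))
  expect_equal(back$pm25, sim$records$pm25)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_identical(cfg$n_stations, nrow(sim$fixture$stations))
  gj <- jsonlite::read_json(file.path(dir, "polygons.geojson"))
  expect_length(gj$features, length(sim$fixture$polygons))
})
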