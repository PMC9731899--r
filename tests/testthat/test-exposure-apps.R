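dates_2013 <- seq(as.Date("2013-01-01"), as.Date("2013-12-31"), by = "day")

test_that("regulatory annual mean is the mean of four quarterly means", {
  # constant series
  expect_equal(regulatory_annual_mean(rep(7.5, 365), dates_2013), 7.5)

  # quarterly means 10, 10, 10, 22 -> 13 regardless of quarter lengths
  q <- (as.integer(format(dates_2013, "%m")) - 1) %/% 3 + 1
  v <- c(10, 10, 10, 22)[q]
  expect_equal(regulatory_annual_mean(v, dates_2013), 13)

  # unbalanced coverage: quarterly-mean and plain-mean definitions differ
  d <- c(dates_2013[q == 1][1:10], dates_2013[q == 2][1:90],
         dates_2013[q == 3][1:90], dates_2013[q == 4][1:90])
  v <- c(rep(40, 10), rep(10, 270))
  expect_equal(regulatory_annual_mean(v, d), 17.5)
  expect_equal(mean(v), 3100 / 280)  # ~11.07: the plain mean disagrees
  expect_false(isTRUE(all.equal(regulatory_annual_mean(v, d), mean(v))))

  # equal day counts per quarter: equals the plain mean
  bal <- unlist(lapply(1:4, function(k) which(q == k)[1:80]))
  vb <- withr::with_seed(8, runif(320, 5, 50))
  expect_equal(regulatory_annual_mean(vb, dates_2013[bal]), mean(vb))

  # an empty quarter leaves the value missing
  expect_message(
    out <- regulatory_annual_mean(rep(10, sum(q != 2)),
                                  dates_2013[q != 2]),
    "empty quarter")
  expect_true(is.na(out))

  expect_error(regulatory_annual_mean(rep(1, 2),
                                      as.Date(c("2012-12-31", "2013-01-01"))),
               "one calendar year")
})

test_that("cell populations are exact area-weighted raster means", {
  # model cell fully inside one raster cell
  r1 <- list(x0 = 0, y0 = 0, dx = 1000, dy = 1000, nx = 2, ny = 1,
             density = matrix(c(100, 300), 2, 1))
  fx1 <- toy_fixture(cx = 500, cy = 500, cell_size = 400, raster = r1)
  p1 <- populate_cells(fx1)
  expect_equal(p1$density, 100)
  expect_equal(p1$persons, 100 * 0.4^2)

  # cell straddling two raster cells in equal halves
  fx2 <- toy_fixture(cx = 1000, cy = 500, cell_size = 400, raster = r1)
  expect_equal(populate_cells(fx2)$density, 200)

  # raster gap under a cell is a hard error
  fx3 <- toy_fixture(cx = 1990, cy = 500, cell_size = 400, raster = r1)
  expect_error(populate_cells(fx3), "does not cover")

  # random offsets: match the exact rectangle-intersection oracle and a
  # fine-subdivision quadrature
  sim <- small_sim()
  pop <- populate_cells(sim$fixture)
  g <- sim$fixture$grid
  half <- sim$fixture$cell_size / 2
  for (i in c(1, 17, nrow(g))) {
    exact <- oracle_cell_density(g$x[i] - half, g$x[i] + half,
                                 g$y[i] - half, g$y[i] + half,
                                 sim$fixture$population)
    expect_equal(pop$density[i], exact, tolerance = 1e-12)
    # fine-subcell midpoint quadrature
    m <- 400
    gx <- g$x[i] - half + (seq_len(m) - 0.5) * sim$fixture$cell_size / m
    gy <- g$y[i] - half + (seq_len(m) - 0.5) * sim$fixture$cell_size / m
    r <- sim$fixture$population
    ix <- findInterval(rep(gx, m), r$x0 + (0:r$nx) * r$dx)
    iy <- findInterval(rep(gy, each = m), r$y0 + (0:r$ny) * r$dy)
    quad <- mean(r$density[cbind(ix, iy)])
    expect_equal(pop$density[i], quad, tolerance = 1e-3)
  }
  # regional total matches the configured fixture population
  expect_equal(sum(pop$persons), 1e5)
})

test_that("compliance arithmetic matches hand and exhaustive oracles", {
  # 2 cells (100, 200 persons) exceeding on 3 and 1 of 4 days
  vals <- rbind(c(50, 50, 50, 10), c(50, 10, 10, 10))
  surf <- make_surface(vals, dates_2013[c(1, 120, 200, 300)])
  pops <- tibble::tibble(cell_id = 1:2, persons = c(100, 200))
  rep1 <- compliance_report(surf, pops, year = 2013)
  expect_equal(rep1$person_days, 100 * 3 + 200 * 1)
  expect_equal(rep1$mean_exceedance_days, 500 / 300)

  # everywhere below both limits: all exceedance quantities zero
  low <- make_surface(matrix(5, 2, 4), dates_2013[c(1, 120, 200, 300)])
  rep0 <- compliance_report(low, pops, year = 2013)
  expect_equal(rep0$person_days, 0)
  expect_equal(rep0$frac_above_annual, 0)
  expect_equal(rep0$mean_exceedance_days, 0)

  # person-days on a simulated year: exhaustive double-loop oracle, and
  # invariance to cell reordering
  sim <- small_sim()
  tr <- sim$truth
  surf2 <- make_surface(tr$mean, tr$dates, cell_id = tr$cell_id)
  pop2 <- populate_cells(sim$fixture)
  rep2 <- compliance_report(surf2, pop2, year = 2012)
  sy <- tr$mean[, format(tr$dates, "%Y") == "2012"]
  # fractional persons: equal up to floating-point summation order
  expect_equal(rep2$person_days,
               oracle_person_days(sy, pop2$persons, 41),
               tolerance = 1e-12)
  perm <- withr::with_seed(5, sample(nrow(tr$mean)))
  surf_p <- make_surface(tr$mean[perm, ], tr$dates,
                         cell_id = tr$cell_id[perm])
  rep_p <- compliance_report(surf_p, pop2, year = 2012)
  expect_equal(rep_p$person_days, rep2$person_days)
})

test_that("population ECDF is a weighted step function with valid quantiles", {
  # degenerate: all cells at v
  surf <- make_surface(matrix(12, 3, 365), dates_2013)
  pops <- tibble::tibble(cell_id = 1:3, persons = c(10, 20, 30))
  e <- population_ecdf(surf, pops, 2013)
  expect_equal(ecdf_quantile(e, c(0.1, 0.9)), c(12, 12))
  expect_equal(max(e$cum_fraction), 1)

  # two-point mass
  surf2 <- make_surface(rbind(rep(10, 365), rep(30, 365)), dates_2013)
  pops2 <- tibble::tibble(cell_id = 1:2, persons = c(5, 5))
  e2 <- population_ecdf(surf2, pops2, 2013)
  expect_equal(e2$cum_fraction, c(0.5, 1))
  expect_equal(e2$concentration, c(10, 30))
  expect_equal(ecdf_quantile(e2, 0.5), 10)
  expect_equal(ecdf_quantile(e2, 0.51), 30)

  # weighted quantiles match a person-level expansion oracle
  withr::with_seed(77, {
    ann <- runif(12, 8, 45)
    persons <- sample(1:50, 12)
  })
  surf3 <- make_surface(matrix(rep(ann, 365), 12), dates_2013)
  e3 <- population_ecdf(surf3, tibble::tibble(cell_id = 1:12,
                                              persons = persons), 2013)
  expanded <- rep(ann, persons)
  for (p in c(0.1, 0.25, 0.5, 0.9)) {
    expect_equal(ecdf_quantile(e3, p),
                 quantile(expanded, p, type = 1, names = FALSE))
  }
  # nondecreasing, ends at 1
  expect_true(all(diff(e3$cum_fraction) >= 0))
  expect_true(all(diff(e3$concentration) >= 0))
})

test_that("daily max:mean ratios and the rain split behave as defined", {
  d6 <- dates_2013[182:187]  # rainy season
  mean_s <- make_surface(matrix(rep(c(10, 20, 10, 40, 25, 10), each = 2),
                                2), d6)
  max_s <- make_surface(2 * mean_s$values, d6)
  precip <- matrix(rep(c(0, 2, 0, 1, 0, 5), each = 2), 2)
  rat <- daily_ratio_series(mean_s, max_s, precip, d6)
  expect_equal(rat$days$ratio, rep(2, 6))
  expect_equal(rat$group_means$mean_ratio, c(2, 2))

  # hand-grouped oracle on distinct ratios
  max_s2 <- make_surface(mean_s$values *
                           rep(c(1.5, 2.5, 2, 3, 1.8, 2.2), each = 2), d6)
  rat2 <- daily_ratio_series(mean_s, max_s2, precip, d6)
  rainy <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  want <- c(mean(rat2$days$ratio[!rainy]), mean(rat2$days$ratio[rainy]))
  expect_equal(rat2$group_means$mean_ratio, want)

  # surfaces from the same hourly truth: ratio always >= 1
  sim <- small_sim()
  agg <- sim$station_days
  expect_true(all(agg$max_pm25 / agg$mean_pm25 >= 1))
})

test_that("kendall tau-b matches pair enumeration, with and without ties", {
  expect_equal(kendall_tau(1:6, (1:6)^3), 1)
  expect_equal(kendall_tau(1:6, rev(1:6)), -1)
  expect_equal(kendall_tau(1:4, c(1, 3, 2, 4)), 2 / 3)
  expect_equal(kendall_tau(c(1, 2, 2, 3), c(1, 2, 3, 3)),
               oracle_tau(c(1, 2, 2, 3), c(1, 2, 3, 3)))
  expect_true(is.na(kendall_tau(rep(1, 5), 1:5)))

  for (s in 1:30) {
    withr::with_seed(4000 + s, {
      n <- sample(3:60, 1)
      x <- sample(1:8, n, replace = TRUE) + rnorm(n, 0, 0.01) *
        rbinom(n, 1, 0.5)
      y <- sample(1:8, n, replace = TRUE)
    })
    expect_equal(kendall_tau(x, y), oracle_tau(x, y), tolerance = 1e-12)
    # symmetry and sign-flip identities
    expect_equal(kendall_tau(y, x), kendall_tau(x, y))
    expect_equal(kendall_tau(x, -y), -kendall_tau(x, y))
  }
  # large-n path (merge sort) agrees with stats::cor
  withr::with_seed(99, {
    x <- round(rnorm(800, 0, 1), 1)
    y <- round(x + rnorm(800, 0, 2), 1)
  })
  expect_equal(kendall_tau(x, y), cor(x, y, method = "kendall"),
               tolerance = 1e-12)
})

test_that("point-in-polygon agrees with winding-number and mgcv oracles", {
  sim <- small_sim()
  for (pg in sim$fixture$polygons) {
    withr::with_seed(17, {
      px <- runif(200, min(pg$xy[, 1]) - 500, max(pg$xy[, 1]) + 500)
      py <- runif(200, min(pg$xy[, 2]) - 500, max(pg$xy[, 2]) + 500)
    })
    got <- point_in_polygon(px, py, pg$xy)
    expect_identical(got, oracle_pip(px, py, pg$xy))
    inout <- mgcv::in.out(rbind(pg$xy, pg$xy[1, ]), cbind(px, py))
    # mgcv draws its own boundary convention; compare off-boundary points
    expect_identical(got, inout)
  }
  # vertices and edge midpoints count as inside
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_true(all(point_in_polygon(c(0, 10, 5, 5), c(0, 10, 0, 5), sq)))
  expect_false(any(point_in_polygon(c(-1, 11), c(5, 5), sq)))
})

test_that("areal linkage averages cells by centroid containment", {
  # polygon containing exactly two centroids with annual means 20 and 30
  fx <- toy_fixture(cx = c(500, 1500, 2500), cy = rep(500, 3),
                    cell_size = 1000,
                    raster = list(x0 = 0, y0 = 0, dx = 3000, dy = 1000,
                                  nx = 1, ny = 1,
                                  density = matrix(1, 1, 1)))
  fx$polygons <- list(
    list(unit_id = "U1", xy = cbind(c(0, 2000, 2000, 0), c(0, 0, 1000, 1000)),
         marginalization = -1.2),
    list(unit_id = "U2", xy = cbind(c(5000, 6000, 6000, 5000),
                                    c(0, 0, 1000, 1000)),
         marginalization = 0.4))
  surf <- make_surface(rbind(rep(20, 365), rep(30, 365), rep(45, 365)),
                       dates_2013)
  al <- areal_link(surf, fx, year = 2013)
  expect_equal(al$units$exposure[1], 25)     # boundary centroid included
  expect_true(is.na(al$units$exposure[2]))   # no centroid
  expect_true(is.na(al$tau))                 # one unit left
  expect_equal(al$bins$bin_low, -1.5)
  expect_equal(al$bins$mean_exposure, 25)
})

test_that("heat co-occurrence partitions cell-days and orients with heat", {
  sim <- small_sim()
  tr <- make_truth_field(sim$fixture, temperature_coupling = 0.5,
                         seasonal_temperature = FALSE,
                         temperature_spatial_sd = 0, seed = 71)
  surf <- make_surface(tr$mean, tr$dates, cell_id = tr$cell_id)
  h <- heat_cooccurrence(surf, tr$temperature)
  expect_equal(h$n_exceedance + sum(!(as.vector(tr$mean) > 41)),
               h$n_cell_days)
  # planted positive coupling: hot days carry more PM
  expect_gt(h$median_pm_hot, h$median_pm_other)
  expect_gt(h$tau, 0)
  expect_gt(h$median_temp_exceedance, h$median_temp_other)
  # conditional quartiles are ordered and cover all cell-days
  expect_true(all(h$conditional_quartiles$q25 <= h$conditional_quartiles$q50))
  expect_true(all(h$conditional_quartiles$q50 <= h$conditional_quartiles$q75))
  expect_equal(sum(h$conditional_quartiles$n), h$n_cell_days)
})
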