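#' Largest connected set of cells under an elevation ceiling
#'
#' Selects the study region the way the exposure model defines it: among
#' grid cells whose elevation does not exceed `ceiling`, keep the largest
#' 4-connected (edge-adjacent) component.  Diagonal adjacency does not
#' connect cells, since square cells share a boundary only along edges.
#'
#' @param elevation numeric matrix of elevations in meters, `n_row x n_col`;
#'   `elevation[r, c]` is the cell in grid row `r`, column `c`.
#' @param ceiling elevation ceiling in meters (default 3000, i.e. 3 km above
#'   sea level).
#' @return Sorted integer vector of cell ids in the largest qualifying
#'   component, with row-major ids `(r - 1) * n_col + c`.  Empty if no cell
#'   qualifies, which signals a misconfigured fixture.
#' @examples
#' e <- matrix(2250, 4, 4)
#' e[1, 4] <- 4000
#' region_mask(e, 3000)
#' @export
region_mask <- function(elevation, ceiling = 3000) {
  stopifnot(is.matrix(elevation), is.finite(ceiling))
  nr <- nrow(elevation)
  nc <- ncol(elevation)
  ok <- is.finite(elevation) & elevation <= ceiling
  comp <- matrix(0L, nr, nc)
  next_comp <- 0L
  best <- integer(0)
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (!ok[r0, c0] || comp[r0, c0] != 0L) next
      next_comp <- next_comp + 1L
      # iterative flood fill, 4-neighbour
      stack <- matrix(c(r0, c0), ncol = 2)
      members <- integer(0)
      comp[r0, c0] <- next_comp
      while (nrow(stack) > 0) {
        r <- stack[nrow(stack), 1]
        c <- stack[nrow(stack), 2]
        stack <- stack[-nrow(stack), , drop = FALSE]
        members <- c(members, (r - 1L) * nc + c)
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          rr <- r + d[1]
          cc <- c + d[2]
          if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
              ok[rr, cc] && comp[rr, cc] == 0L) {
            comp[rr, cc] <- next_comp
            stack <- rbind(stack, c(rr, cc))
          }
        }
      }
      if (length(members) > length(best)) best <- members
    }
  }
  sort(best)
}

#' Generate a synthetic study-region fixture
#'
#' Builds a self-contained toy analogue of a high-altitude metropolitan
#' study region: a square grid of projected cells with elevations, a
#' monitoring network, simple scored polygons standing in for census units,
#' and a population-density raster on its own, deliberately misaligned grid.
#' All randomness derives from `seed` and generation is reproducible.
#'
#' The default scale (20 x 20 cells of 927 m, 8 stations, 2 calendar years,
#' 6 polygons) is a down-scaled version of the full-study geometry (thousands
#' of ~1 km cells, ~25 stations, 16 years) chosen so that a complete
#' cross-validated analysis runs in minutes.
#'
#' @param n_row,n_col grid dimensions.
#' @param cell_size cell side in meters.
#' @param n_stations number of monitoring stations, placed in distinct cells.
#' @param start_year first simulated calendar year.
#' @param n_years number of whole calendar years.
#' @param n_polygons number of scored areal units.
#' @param total_population total persons in the region; the population raster
#'   is scaled so that area-weighted cell populations sum to this.
#' @param elevation_ceiling meters; cells above it are excluded from the
#'   region mask.
#' @param seed integer seed.
#' @return An object of class `region_fixture`: a list with `grid` (tibble of
#'   in-region cells: `cell_id`, `row`, `col`, `x`, `y`, `elevation`),
#'   `cell_size`, `n_row`, `n_col`, `stations` (tibble `station_id`, `x`,
#'   `y`, `cell_id`), `polygons` (list of `unit_id`, `xy` vertex matrix,
#'   `marginalization`), `population` (raster list: `x0`, `y0`, `dx`, `dy`,
#'   `nx`, `ny`, `density` matrix in persons/km^2), `dates`, and `seed`.
#' @export
make_region_fixture <- function(n_row = 20, n_col = 20, cell_size = 927,
                                n_stations = 8, start_year = 2012,
                                n_years = 2, n_polygons = 6,
                                total_population = 1e6,
                                elevation_ceiling = 3000, seed = 1) {
  stopifnot(n_row >= 4, n_col >= 4, cell_size > 0, n_stations >= 2,
            n_years >= 1, n_polygons >= 1, total_population > 0)
  with_seed(seed, {
    # Plateau with smooth relief plus one mountain corner poking above the
    # ceiling, so the mask exercise is non-trivial.
    rows <- rep(seq_len(n_row), each = n_col)
    cols <- rep(seq_len(n_col), times = n_row)
    x <- (cols - 0.5) * cell_size
    y <- (rows - 0.5) * cell_size
    relief <- gauss_smooth_field(x, y, ell = 3 * cell_size)
    ridge <- 1800 * exp(-0.5 * (((x - n_col * cell_size)^2 +
                                 (y - n_row * cell_size)^2) /
                                (2.2 * cell_size)^2))
    elevation <- 2250 + 120 * relief + ridge
    elev_mat <- matrix(elevation, n_row, n_col, byrow = TRUE)
    mask <- region_mask(elev_mat, elevation_ceiling)
    if (length(mask) == 0) stop("no cell qualifies under the elevation ceiling")

    all_ids <- (rows - 1L) * n_col + cols
    keep <- all_ids %in% mask
    grid <- tibble::tibble(
      cell_id = all_ids[keep], row = rows[keep], col = cols[keep],
      x = x[keep], y = y[keep], elevation = elevation[keep]
    )
    grid <- grid[order(grid$cell_id), ]

    # Stations in distinct in-region cells, jittered off the centroid.
    host <- sample(grid$cell_id, n_stations)
    hi <- match(host, grid$cell_id)
    stations <- tibble::tibble(
      station_id = sprintf("ST%02d", seq_len(n_stations)),
      x = grid$x[hi] + runif(n_stations, -0.3, 0.3) * cell_size,
      y = grid$y[hi] + runif(n_stations, -0.3, 0.3) * cell_size,
      cell_id = host
    )

    # Star-shaped (hence simple) polygons around random in-region centers,
    # with real-valued deprivation scores on roughly the index's scale.
    polygons <- lapply(seq_len(n_polygons), function(i) {
      ci <- sample(nrow(grid), 1)
      k <- sample(6:9, 1)
      ang <- sort(runif(k, 0, 2 * pi))
      rad <- runif(k, 1.2, 3.2) * cell_size
      list(
        unit_id = sprintf("U%02d", i),
        xy = cbind(x = grid$x[ci] + rad * cos(ang),
                   y = grid$y[ci] + rad * sin(ang)),
        marginalization = round(max(-2.4, min(2.4, rnorm(1, 0, 1.1))), 3)
      )
    })

    # Population raster on its own grid: coarser cells, offset origin.
    dx <- dy <- 1100
    x0 <- -dx + 350
    y0 <- -dy - 410
    nx <- ceiling((n_col * cell_size - x0) / dx) + 1L
    ny <- ceiling((n_row * cell_size - y0) / dy) + 1L
    rc_x <- x0 + (seq_len(nx) - 0.5) * dx
    rc_y <- y0 + (seq_len(ny) - 0.5) * dy
    rx <- rep(rc_x, times = ny)
    ry <- rep(rc_y, each = nx)
    pf <- gauss_smooth_field(rx, ry, ell = 4 * cell_size)
    density <- matrix(exp(0.8 * pf), nx, ny)

    dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
                 as.Date(sprintf("%d-12-31", start_year + n_years - 1)),
                 by = "day")

    fixture <- structure(
      list(grid = grid, cell_size = cell_size, n_row = n_row, n_col = n_col,
           stations = stations, polygons = polygons,
           population = list(x0 = x0, y0 = y0, dx = dx, dy = dy,
                             nx = nx, ny = ny, density = density),
           dates = dates, seed = as.integer(seed)),
      class = "region_fixture"
    )
    # Scale the raster so implied in-region population matches the target.
    pop <- populate_cells(fixture)
    fixture$population$density <-
      fixture$population$density * total_population / sum(pop$persons)
    fixture
  })
}

#' @export
print.region_fixture <- function(x, ...) {
  cat("<region_fixture> ", nrow(x$grid), " cells (", x$n_row, "x", x$n_col,
      " grid, ", x$cell_size, " m side), ", nrow(x$stations), " stations, ",
      length(x$polygons), " polygons, ", length(x$dates), " days, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}
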