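# Independent brute-force oracles.  Each deliberately uses a different
# algorithm or library than the implementation it checks.

# Largest low-elevation connected component via igraph, 4-neighbour.
oracle_largest_component <- function(elevation, ceiling) {
  nr <- nrow(elevation)
  nc <- ncol(elevation)
  id <- function(r, c) (r - 1L) * nc + c
  ok <- which(elevation <= ceiling, arr.ind = TRUE)
  if (nrow(ok) == 0) return(integer(0))
  ok_ids <- id(ok[, 1], ok[, 2])
  edges <- c()
  for (k in seq_len(nrow(ok))) {
    r <- ok[k, 1]; c <- ok[k, 2]
    if (r < nr && elevation[r + 1, c] <= ceiling) {
      edges <- c(edges, id(r, c), id(r + 1, c))
    }
    if (c < nc && elevation[r, c + 1] <= ceiling) {
      edges <- c(edges, id(r, c), id(r, c + 1))
    }
  }
  g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2,
                                          byrow = TRUE), directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(ok_ids),
                                    igraph::V(g)$name))
  comp <- igraph::components(g)
  biggest <- which.max(comp$csize)
  sort(as.integer(igraph::V(g)$name[comp$membership == biggest]))
}

# Direct weighted-sum IDW, scalar loops.
oracle_idw <- function(tx, ty, sx, sy, v, exponent = 2, eps = 1) {
  vapply(seq_along(tx), function(i) {
    d <- sqrt((tx[i] - sx)^2 + (ty[i] - sy)^2)
    if (any(d < eps)) return(v[which(d < eps)[1]])
    w <- d^(-exponent)
    sum(w * v) / sum(w)
  }, numeric(1))
}

# O(n^2) pair-enumeration Kendall tau-b.
oracle_tau <- function(x, y) {
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  num <- sum((dx * dy)[up])
  n0 <- sum(up)
  n1 <- sum(dx[up] == 0)
  n2 <- sum(dy[up] == 0)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) NA_real_ else num / den
}

# Winding-number point-in-polygon (angle summation), boundary-inclusive.
oracle_pip <- function(px, py, xy, eps = 1e-6) {
  n <- nrow(xy)
  seg_dist <- function(x, y, x1, y1, x2, y2) {
    l2 <- (x2 - x1)^2 + (y2 - y1)^2
    t <- if (l2 > 0) ((x - x1) * (x2 - x1) + (y - y1) * (y2 - y1)) / l2 else 0
    t <- min(max(t, 0), 1)
    sqrt((x - (x1 + t * (x2 - x1)))^2 + (y - (y1 + t * (y2 - y1)))^2)
  }
  vapply(seq_along(px), function(k) {
    ang <- 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      if (seg_dist(px[k], py[k], xy[i, 1], xy[i, 2],
                   xy[j, 1], xy[j, 2]) <= eps) {
        return(TRUE)
      }
      ax <- xy[i, 1] - px[k]; ay <- xy[i, 2] - py[k]
      bx <- xy[j, 1] - px[k]; by <- xy[j, 2] - py[k]
      ang <- ang + atan2(ax * by - ay * bx, ax * bx + ay * by)
    }
    abs(ang) > pi
  }, logical(1))
}

# Area-weighted raster density for one axis-aligned cell: full double loop
# over every raster cell with exact rectangle-intersection areas.
oracle_cell_density <- function(xlo, xhi, ylo, yhi, raster) {
  tot_w <- 0
  tot <- 0
  for (ix in seq_len(raster$nx)) {
    for (iy in seq_len(raster$ny)) {
      rx0 <- raster$x0 + (ix - 1) * raster$dx
      ry0 <- raster$y0 + (iy - 1) * raster$dy
      ox <- max(0, min(xhi, rx0 + raster$dx) - max(xlo, rx0))
      oy <- max(0, min(yhi, ry0 + raster$dy) - max(ylo, ry0))
      tot_w <- tot_w + ox * oy
      tot <- tot + ox * oy * raster$density[ix, iy]
    }
  }
  tot / tot_w
}

# Person-days of exceedance by exhaustive double loop.
oracle_person_days <- function(values, persons, limit) {
  total <- 0
  for (i in seq_len(nrow(values))) {
    for (j in seq_len(ncol(values))) {
      if (values[i, j] > limit) total <- total + persons[i]
    }
  }
  total
}

# Metric definitions re-implemented with explicit loops.
oracle_metrics <- function(o, p) {
  n <- length(o)
  mae <- sum(abs(o - p)) / n
  mse <- sum((o - p)^2) / n
  mu <- sum(o) / n
  v <- sum((o - mu)^2) / n
  med <- sort(o)[ceiling(n / 2)]
  if (n %% 2 == 0) med <- (sort(o)[n / 2] + sort(o)[n / 2 + 1]) / 2
  list(MAE = mae, RMSE = sqrt(mse), SD = sqrt(v),
       MAD = sum(abs(o - med)) / n,
       R2 = if (v > 0) 1 - mse / v else NA_real_)
}
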