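# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so simulation calls do not disturb the
# session RNG stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Population (divide-by-n) variance; the R^2 and SD conventions of the
# evaluation module are fixed to this.
pop_var <- function(x) mean((x - mean(x))^2)

# Smooth a white-noise vector over planar coordinates with a Gaussian kernel
# of range `ell` (same units as x/y), then restandardise to mean 0 / sd 1.
# This is the generator's stand-in for a spatially correlated random field.
gauss_smooth_field <- function(x, y, ell, z = rnorm(length(x))) {
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  k <- exp(-0.5 * d2 / ell^2)
  f <- as.vector(k %*% z) / rowSums(k)
  (f - mean(f)) / max(sd(f), .Machine$double.eps)
}

# Standardise a numeric vector/matrix by its overall mean and sd.
zscore <- function(x) {
  mu <- mean(x, na.rm = TRUE)
  s <- sd(as.vector(x), na.rm = TRUE)
  (x - mu) / max(s, .Machine$double.eps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

month_of <- function(date) as.integer(format(date, "%m"))
year_of <- function(date) as.integer(format(date, "%Y"))
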