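# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs the code, and restores the caller's RNG state so that
#' seeded generators do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Trilinear interpolation of a 3-D array at continuous 0-based voxel
# coordinates. Points outside the grid support return `fill`.
interp3 <- function(arr, x, y, z, fill = 0) {
  d <- dim(arr)
  out <- rep(fill, length(x))
  eps <- 1e-9
  ok <- x >= -eps & x <= d[1] - 1 + eps &
        y >= -eps & y <= d[2] - 1 + eps &
        z >= -eps & z <= d[3] - 1 + eps
  if (!any(ok)) return(out)
  x <- pmin(pmax(x[ok], 0), d[1] - 1)
  y <- pmin(pmax(y[ok], 0), d[2] - 1)
  z <- pmin(pmax(z[ok], 0), d[3] - 1)
  x0 <- pmin(floor(x), d[1] - 2); fx <- x - x0
  y0 <- pmin(floor(y), d[2] - 2); fy <- y - y0
  z0 <- pmin(floor(z), d[3] - 2); fz <- z - z0
  # 1-based linear indices of the 8 cube corners
  i000 <- (x0 + 1) + d[1] * y0 + d[1] * d[2] * z0
  dx <- 1; dy <- d[1]; dz <- d[1] * d[2]
  v <- (1 - fx) * (1 - fy) * (1 - fz) * arr[i000] +
       fx       * (1 - fy) * (1 - fz) * arr[i000 + dx] +
       (1 - fx) * fy       * (1 - fz) * arr[i000 + dy] +
       fx       * fy       * (1 - fz) * arr[i000 + dx + dy] +
       (1 - fx) * (1 - fy) * fz       * arr[i000 + dz] +
       fx       * (1 - fy) * fz       * arr[i000 + dx + dz] +
       (1 - fx) * fy       * fz       * arr[i000 + dy + dz] +
       fx       * fy       * fz       * arr[i000 + dx + dy + dz]
  out[ok] <- v
  out
}

# Apply a matrix K (n x n) along one axis of a 3-D array.
apply_axis <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  a <- K %*% matrix(a, d[axis])
  a <- array(a, d[perm])
  aperm(a, order(perm))
}

# Mode-n product of a 3-D array with a matrix M (rows_out x dim_n(arr)).
mode_product <- function(arr, M, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  a <- M %*% matrix(a, d[axis])
  a <- array(a, c(nrow(M), d[perm][-1]))
  aperm(a, order(perm))
}

# 0-based voxel coordinates (n x 3) to homogeneous world (n x 3) via affine.
voxel_to_world <- function(vox, affine) {
  vox <- rbind(t(vox), 1)
  t(affine %*% vox)[, 1:3, drop = FALSE]
}

world_to_voxel <- function(world, affine) {
  voxel_to_world(world, solve(affine))
}

# Full strided 0-based index grids as an n x 3 matrix plus the index vectors.
strided_grid <- function(shape, stride = 1L) {
  ix <- seq(0L, shape[1] - 1L, by = stride)
  iy <- seq(0L, shape[2] - 1L, by = stride)
  iz <- seq(0L, shape[3] - 1L, by = stride)
  g <- as.matrix(expand.grid(x = ix, y = iy, z = iz))
  list(coords = g, ix = ix, iy = iy, iz = iz,
       n = c(length(ix), length(iy), length(iz)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
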