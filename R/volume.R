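# Core volume / VOI-mask data model and NIfTI-1 I/O.

#' Construct a 3-D scalar volume
#'
#' The unit of all image processing in the package: a 3-D grid of intensities
#' (arbitrary units) together with its voxel spacing and a 4x4 voxel-to-world
#' affine (0-based voxel indices, world coordinates in mm, RAS-oriented by
#' default with the origin at the grid centre).
#'
#' @param data numeric 3-D array; every dimension must be at least 8.
#' @param voxel_size length-3 positive numeric, mm per voxel.
#' @param affine 4x4 voxel-to-world matrix; default is axis-aligned RAS with
#'   the world origin at the volume centre.
#' @param space `"native"` or `"template"`.
#' @return an object of class `volume`.
#' @export
new_volume <- function(data, voxel_size = c(1, 1, 1), affine = NULL,
                       space = c("native", "template")) {
  space <- match.arg(space)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3-D array, got ", length(dim(data)), " dimension(s)")
  d <- dim(data)
  if (any(d < 8L))
    stop("all grid dimensions must be >= 8; got ", paste(d, collapse = "x"))
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three strictly positive values")
  if (is.null(affine)) affine <- default_affine(d, voxel_size)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix")
  structure(list(data = data, voxel_size = voxel_size, affine = affine,
                 space = space),
            class = "volume")
}

# Centred RAS affine for a grid.
default_affine <- function(shape, voxel_size) {
  a <- diag(4)
  a[1:3, 1:3] <- diag(voxel_size, 3)
  a[1:3, 4] <- -voxel_size * (shape - 1) / 2
  a
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume> %s space, %s voxels, %.3g x %.3g x %.3g mm\n",
              x$space, paste(dim(x$data), collapse = "x"),
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a binary volume of interest (VOI) mask
#'
#' @param data 3-D array containing only 0/1 (or logical); at least one voxel
#'   must be set.
#' @param role one of `"striatum_left"`, `"striatum_right"`,
#'   `"striatum_bilateral"`, `"reference"`.
#' @inheritParams new_volume
#' @return an object of class `voi_mask` (which also inherits from `volume`).
#' @export
new_voi_mask <- function(data, role = c("striatum_left", "striatum_right",
                                        "striatum_bilateral", "reference"),
                         voxel_size = c(1, 1, 1), affine = NULL,
                         space = c("native", "template")) {
  role <- match.arg(role)
  if (is.logical(data)) data <- array(as.numeric(data), dim(data))
  u <- unique(as.vector(data))
  if (!all(u %in% c(0, 1)))
    stop("mask voxels must all be 0 or 1")
  if (sum(data) < 1)
    stop("empty mask: a VOI must contain at least one voxel")
  v <- new_volume(data, voxel_size = voxel_size, affine = affine, space = space)
  v$role <- role
  class(v) <- c("voi_mask", "volume")
  v
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> role %s, %s space, %d voxels set\n",
              x$role, x$space, sum(x$data)))
  invisible(x)
}

check_congruent <- function(a, b) {
  if (!all(dim(a$data) == dim(b$data)))
    stop("grid shape mismatch: ", paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"))
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' Reads a (optionally gzipped) NIfTI-1 file. Intensities are taken as stored
#' after the header's scale slope/intercept; no further rescaling is applied.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param space space tag to attach (`"native"` or `"template"`).
#' @return a [new_volume()] object.
#' @export
read_volume <- function(path, space = c("native", "template")) {
  space <- match.arg(space)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D image, got a ", length(d), "-D image: ", path)
  aff <- structure(RNifti::xform(img), dimnames = NULL)
  if (abs(det(aff)) < 1e-12) stop("degenerate affine in ", path)
  vs <- RNifti::pixdim(img)[1:3]
  new_volume(array(as.numeric(img), d), voxel_size = vs, affine = aff,
             space = space)
}

#' Read a NIfTI-1 VOI mask
#'
#' @inheritParams read_volume
#' @param role the VOI role to attach.
#' @return a [new_voi_mask()] object.
#' @export
read_voi_mask <- function(path, role, space = c("native", "template")) {
  space <- match.arg(space)
  v <- read_volume(path, space = space)
  new_voi_mask(v$data, role = role, voxel_size = v$voxel_size,
               affine = v$affine, space = space)
}

#' Write a volume or mask as NIfTI-1
#'
#' Masks (class `voi_mask`) are written as unsigned 8-bit, other volumes as
#' 64-bit float so that read/write roundtrips are bit-lossless.
#'
#' @param v a `volume` or `voi_mask`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return the path, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  datatype <- if (inherits(v, "voi_mask")) "uint8" else "double"
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$voxel_size
  RNifti::qform(img) <- structure(v$affine, code = 2L)
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Gaussian smoothing of a volume
#'
#' Isotropic smoothing specified as full width at half maximum in mm; the
#' per-axis kernel sigma is `fwhm_mm / (voxel_size * 2.35482)` voxels.
#' Boundaries are handled by nearest-edge extension, so constant images are
#' fixed points and interior mass is conserved.
#'
#' @param v a `volume`.
#' @param fwhm_mm non-negative smoothing width in mm; 0 returns `v` unchanged.
#' @return the smoothed `volume`.
#' @export
gaussian_smooth <- function(v, fwhm_mm) {
  stopifnot(inherits(v, "volume"))
  if (length(fwhm_mm) != 1L || is.na(fwhm_mm) || fwhm_mm < 0)
    stop("fwhm_mm must be a single non-negative number")
  if (fwhm_mm == 0) return(v)
  sigma_vox <- fwhm_mm / (v$voxel_size * 2.35482)
  out <- v$data
  for (ax in 1:3) {
    K <- smoothing_matrix(dim(v$data)[ax], sigma_vox[ax])
    out <- apply_axis(out, K, ax)
  }
  v$data <- out
  v
}

# Band matrix implementing 1-D Gaussian convolution with replicated edges.
smoothing_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- stats::dnorm(seq(-r, r) / sigma_vox)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  rows <- seq_len(n)
  for (off in seq(-r, r)) {
    j <- pmin(pmax(rows + off, 1L), n)
    idx <- cbind(rows, j)
    K[idx] <- K[idx] + k[off + r + 1]
  }
  K
}

#' Mean intensity within a VOI
#'
#' @param v a `volume`.
#' @param m a `voi_mask` on the same grid.
#' @return the arithmetic mean of `v` over voxels where the mask is 1.
#' @export
mean_in_mask <- function(v, m) {
  stopifnot(inherits(v, "volume"), inherits(m, "voi_mask"))
  check_congruent(v, m)
  if (sum(m$data) < 1) stop("empty mask")
  sum(v$data * m$data) / sum(m$data)
}
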