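# Spatial normalization: 12-DOF affine + low-frequency cosine-basis
# deformation, transform serialization, fixed-point inversion, and transfer
# of template-space VOIs into native space.

#' Registration parameters
#'
#' Defaults follow the normalization settings used for DAT-SPECT template
#' matching: sixteen nonlinear iterations, unit regularization, 8-mm FWHM
#' smoothing of the source image and no smoothing of the template.
#'
#' @param nonlinear_iterations number of Gauss-Newton steps for the
#'   deformation stage (run exactly).
#' @param regularization_weight weight on the bending-energy penalty of the
#'   displacement field.
#' @param source_smoothing_fwhm_mm,template_smoothing_fwhm_mm internal
#'   smoothing applied before cost evaluation.
#' @param basis_cutoff_mm shortest spatial period (mm) of the cosine basis
#'   parameterizing the deformation; must exceed twice the largest voxel size.
#' @param affine_dof degrees of freedom of the affine stage (fixed at 12).
#' @param affine_max_iter,affine_tol iteration cap and relative-SSD
#'   convergence tolerance for the affine stage.
#' @param sampling_stride voxel stride at which the cost function samples the
#'   template grid; 1 (default) samples every template voxel, 2 trades
#'   accuracy for an eight-fold cost reduction.
#' @return an object of class `registration_params`.
#' @export
registration_params <- function(nonlinear_iterations = 16,
                                regularization_weight = 1,
                                source_smoothing_fwhm_mm = 8,
                                template_smoothing_fwhm_mm = 0,
                                basis_cutoff_mm = 75,
                                affine_dof = 12,
                                affine_max_iter = 40,
                                affine_tol = 1e-4,
                                sampling_stride = 1L) {
  if (nonlinear_iterations < 1) stop("nonlinear_iterations must be >= 1")
  if (regularization_weight < 0) stop("regularization_weight must be >= 0")
  if (source_smoothing_fwhm_mm < 0 || template_smoothing_fwhm_mm < 0)
    stop("smoothing FWHM must be >= 0")
  if (affine_dof != 12) stop("only the 12-parameter affine is supported")
  structure(list(nonlinear_iterations = as.integer(nonlinear_iterations),
                 regularization_weight = regularization_weight,
                 source_smoothing_fwhm_mm = source_smoothing_fwhm_mm,
                 template_smoothing_fwhm_mm = template_smoothing_fwhm_mm,
                 basis_cutoff_mm = basis_cutoff_mm,
                 affine_dof = 12L,
                 affine_max_iter = as.integer(affine_max_iter),
                 affine_tol = affine_tol,
                 sampling_stride = as.integer(sampling_stride)),
            class = "registration_params")
}

grid_spec <- function(v) {
  if (inherits(v, "volume"))
    list(shape = dim(v$data), voxel_size = v$voxel_size, affine = v$affine)
  else v
}

new_transform <- function(affine, coeffs = NULL, basis_dims = NULL,
                          template_grid = NULL, converged = TRUE) {
  structure(list(affine = affine, coeffs = coeffs, basis_dims = basis_dims,
                 template_grid = template_grid, converged = converged),
            class = "srr_transform")
}

#' @export
print.srr_transform <- function(x, ...) {
  cat("<srr_transform> template-world -> native-world\n")
  cat("  affine:\n")
  print(round(x$affine, 4))
  if (!is.null(x$coeffs))
    cat(sprintf("  deformation: %s cosine basis, coefficient RMS %.4g mm\n",
                paste(x$basis_dims, collapse = "x"),
                sqrt(mean(x$coeffs^2))))
  invisible(x)
}

# Orthonormal DCT-II basis evaluated at 0-based grid indices (n x k).
dct_basis <- function(n, k) {
  i <- seq(0, n - 1)
  B <- sapply(seq(0, k - 1), function(m)
    cos(pi * m * (2 * i + 1) / (2 * n)))
  B <- matrix(B, n, k)
  B[, 1] <- B[, 1] * sqrt(1 / n)
  if (k > 1) B[, -1] <- B[, -1] * sqrt(2 / n)
  B
}

basis_size <- function(shape, voxel_size, cutoff_mm) {
  fov <- shape * voxel_size
  pmax(2L, pmin(shape, as.integer(floor(2 * fov / cutoff_mm))))
}

# Dense displacement field (nx, ny, nz, 3) in template-world mm from
# coefficients (K x 3).
coeffs_to_field <- function(coeffs, basis_dims, shape) {
  Bx <- dct_basis(shape[1], basis_dims[1])
  By <- dct_basis(shape[2], basis_dims[2])
  Bz <- dct_basis(shape[3], basis_dims[3])
  out <- array(0, c(shape, 3))
  for (c in 1:3) {
    a <- array(coeffs[, c], basis_dims)
    a <- mode_product(a, Bx, 1)
    a <- mode_product(a, By, 2)
    a <- mode_product(a, Bz, 3)
    out[, , , c] <- a
  }
  out
}

# Central-difference gradient arrays of a 3-D volume (per voxel unit).
gradient_arrays <- function(arr) {
  d <- dim(arr)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  gx[2:(d[1] - 1), , ] <- (arr[3:d[1], , ] - arr[1:(d[1] - 2), , ]) / 2
  gy[, 2:(d[2] - 1), ] <- (arr[, 3:d[2], ] - arr[, 1:(d[2] - 2), ]) / 2
  gz[, , 2:(d[3] - 1)] <- (arr[, , 3:d[3]] - arr[, , 1:(d[3] - 2)]) / 2
  list(gx, gy, gz)
}

# Shared setup for both registration stages.
reg_setup <- function(source, template, params) {
  src <- gaussian_smooth(source, params$source_smoothing_fwhm_mm)
  tpl <- gaussian_smooth(template, params$template_smoothing_fwhm_mm)
  if (stats::var(as.vector(tpl$data)) == 0 ||
      stats::var(as.vector(src$data)) == 0)
    stop("degenerate (constant) image: registration cost has no gradient")
  g <- strided_grid(dim(tpl$data), params$sampling_stride)
  wt <- voxel_to_world(g$coords, tpl$affine)
  grad <- gradient_arrays(src$data)
  # native world -> native voxel, and gradient chain voxel -> world
  n2v <- solve(source$affine)
  ginvT <- t(solve(source$affine[1:3, 1:3]))
  list(src = src, tpl = tpl, grid = g, wt = wt, grad = grad,
       n2v = n2v, ginvT = ginvT,
       gvals = tpl$data[1 + g$coords[, 1] +
                        dim(tpl$data)[1] * g$coords[, 2] +
                        dim(tpl$data)[1] * dim(tpl$data)[2] * g$coords[, 3]])
}

# Sample the smoothed source and its world-space gradient at native world
# coordinates (n x 3). Returns f, and gradient matrix (n x 3).
sample_source <- function(setup, wn) {
  vn <- cbind(wn, 1) %*% t(setup$n2v)
  f <- interp3(setup$src$data, vn[, 1], vn[, 2], vn[, 3])
  gv <- cbind(interp3(setup$grad[[1]], vn[, 1], vn[, 2], vn[, 3]),
              interp3(setup$grad[[2]], vn[, 1], vn[, 2], vn[, 3]),
              interp3(setup$grad[[3]], vn[, 1], vn[, 2], vn[, 3]))
  list(f = f, gw = gv %*% setup$ginvT)
}

#' Estimate the affine stage of spatial normalization
#'
#' Finds the 12-parameter affine (template world to native world) minimizing
#' the sum of squared differences between the smoothed source resampled into
#' template space and the template, with a global intensity scale re-estimated
#' every iteration. Deterministic Gauss-Newton from the identity.
#'
#' @param source native-space `volume`.
#' @param template template-space `volume`.
#' @param params a [registration_params()].
#' @return an `srr_transform` with affine only.
#' @export
estimate_affine <- function(source, template, params = registration_params()) {
  setup <- reg_setup(source, template, params)
  g <- setup$gvals
  M <- diag(4)
  best <- list(ssd = Inf, M = M)
  converged <- FALSE
  stagnant <- 0L
  wt_h <- cbind(setup$wt, 1)
  for (it in seq_len(params$affine_max_iter)) {
    wn <- wt_h %*% t(M[1:3, , drop = FALSE])
    sf <- sample_source(setup, wn)
    s <- sum(sf$f * g) / max(sum(sf$f^2), .Machine$double.eps)
    r <- s * sf$f - g
    ssd <- sum(r^2)
    # convergence = SSD no longer improving by more than the relative tolerance
    if (ssd < best$ssd * (1 - params$affine_tol)) {
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
      if (stagnant >= 2L) {
        if (ssd < best$ssd) best <- list(ssd = ssd, M = M)
        converged <- TRUE
        break
      }
    }
    if (ssd < best$ssd) best <- list(ssd = ssd, M = M)
    # Jacobian wrt the 12 entries of M[1:3, ]: d r / d M_ij = s * gw_i * wt_j
    J <- matrix(0, length(r), 12)
    for (i in 1:3) for (j in 1:4)
      J[, (i - 1) * 4 + j] <- s * sf$gw[, i] * wt_h[, j]
    JtJ <- crossprod(J)
    rhs <- -crossprod(J, r)
    lam <- 1e-7 * mean(diag(JtJ))
    delta <- tryCatch(solve(JtJ + diag(lam, 12), rhs),
                      error = function(e) solve(JtJ + diag(1e-3 * mean(diag(JtJ)), 12), rhs))
    M[1:3, ] <- M[1:3, ] + matrix(delta, 3, 4, byrow = TRUE)
  }
  if (!converged)
    warning("affine registration did not converge within the iteration cap; ",
            "returning the best iterate")
  new_transform(affine = best$M, template_grid = grid_spec(template),
                converged = converged)
}

#' Estimate the nonlinear stage of spatial normalization
#'
#' The displacement field (template-world mm) is parameterized by a 3-D
#' separable cosine (DCT) basis whose shortest spatial period is
#' `basis_cutoff_mm`. The objective is SSD plus `regularization_weight` times
#' the bending energy of the displacement, which is diagonal in the cosine
#' basis. Runs exactly `nonlinear_iterations` Gauss-Newton steps; singular
#' normal equations fall back to a ridge-stabilized step with a warning.
#'
#' @inheritParams estimate_affine
#' @param start an `srr_transform` holding the affine to start from.
#' @return an `srr_transform` with affine and deformation coefficients.
#' @export
estimate_nonlinear <- function(source, template, start,
                               params = registration_params()) {
  stopifnot(inherits(start, "srr_transform"))
  tgrid <- grid_spec(template)
  if (params$basis_cutoff_mm <= 2 * max(tgrid$voxel_size))
    stop("basis_cutoff_mm must exceed twice the largest voxel size")
  setup <- reg_setup(source, template, params)
  g <- setup$gvals
  A <- start$affine
  Alin <- A[1:3, 1:3]
  shape <- tgrid$shape
  nb <- basis_size(shape, tgrid$voxel_size, params$basis_cutoff_mm)
  K <- prod(nb)
  # basis matrices at the sampled grid positions
  Bxs <- dct_basis(shape[1], nb[1])[setup$grid$ix + 1, , drop = FALSE]
  Bys <- dct_basis(shape[2], nb[2])[setup$grid$iy + 1, , drop = FALSE]
  Bzs <- dct_basis(shape[3], nb[3])[setup$grid$iz + 1, , drop = FALSE]
  nxs <- nrow(Bxs); nys <- nrow(Bys); nzs <- nrow(Bzs)
  # in-plane design: Kxy[(x fastest, y), (i fastest, j)] = Bxs[x, i] * Bys[y, j]
  Kxy <- matrix(0, nxs * nys, nb[1] * nb[2])
  for (j in seq_len(nb[2])) {
    cols <- (j - 1) * nb[1] + seq_len(nb[1])
    Kxy[, cols] <- Bxs[rep(seq_len(nxs), nys), , drop = FALSE] *
                   rep(Bys[, j], each = nxs)
  }
  # bending-energy diagonal, (wx^2 + wy^2 + wz^2)^2 per basis function, plus a
  # weak zeroth-order shrinkage that bounds the constant/linear displacement
  # directions the bending energy leaves free
  fov <- shape * tgrid$voxel_size
  om <- function(k, L) (pi * seq(0, k - 1) / L)^2
  w2 <- outer(outer(om(nb[1], fov[1]), om(nb[2], fov[2]), "+"),
              om(nb[3], fov[3]), "+")
  Hdiag <- as.vector(w2^2) + (2 * pi / 300)^4
  lam <- params$regularization_weight * 6e-5 * sum(g^2)
  coeffs <- matrix(0, K, 3)
  nvox_slice <- nxs * nys
  wt <- setup$wt
  for (it in seq_len(params$nonlinear_iterations)) {
    # displacement at sampled points
    Ds <- sapply(1:3, function(c) {
      a <- array(coeffs[, c], nb)
      a <- mode_product(a, Bxs, 1)
      a <- mode_product(a, Bys, 2)
      a <- mode_product(a, Bzs, 3)
      as.vector(a)
    })
    wn <- cbind(wt + Ds, 1) %*% t(A[1:3, , drop = FALSE])
    sf <- sample_source(setup, wn)
    s <- sum(sf$f * g) / max(sum(sf$f^2), .Machine$double.eps)
    r <- s * sf$f - g
    gd <- s * (sf$gw %*% Alin)  # d(residual)/d(displacement component)
    # normal equations via per-slice Kronecker accumulation
    G <- matrix(0, 3 * K, 3 * K)
    rhs <- numeric(3 * K)
    Cs <- array(0, c(ncol(Kxy), ncol(Kxy)))
    for (d in 1:3) {
      Wr <- array(gd[, d] * r, c(nxs, nys, nzs))
      a <- mode_product(Wr, t(Bxs), 1)
      a <- mode_product(a, t(Bys), 2)
      a <- mode_product(a, t(Bzs), 3)
      rhs[(d - 1) * K + seq_len(K)] <- as.vector(a)
      for (e in d:3) {
        blk <- matrix(0, K, K)
        for (z in seq_len(nzs)) {
          rows <- (z - 1) * nvox_slice + seq_len(nvox_slice)
          A1 <- Kxy * gd[rows, d]
          A2 <- if (e == d) A1 else Kxy * gd[rows, e]
          Cs <- crossprod(A1, A2)
          blk <- blk + kronecker(tcrossprod(Bzs[z, ]), Cs)
        }
        ri <- (d - 1) * K + seq_len(K)
        ci <- (e - 1) * K + seq_len(K)
        G[ri, ci] <- blk
        if (e != d) G[ci, ri] <- t(blk)
      }
    }
    Hfull <- rep(lam * Hdiag, 3)
    rhs_full <- -(rhs + Hfull * as.vector(coeffs))
    lhs <- G + diag(Hfull + 1e-8 * mean(diag(G)), 3 * K)
    delta <- tryCatch(solve(lhs, rhs_full), error = function(e) {
      warning("singular normal equations in nonlinear registration; ",
              "taking a ridge-stabilized step")
      solve(lhs + diag(1e-2 * mean(diag(G)), 3 * K), rhs_full)
    })
    coeffs <- coeffs + matrix(delta, K, 3)
  }
  new_transform(affine = A, coeffs = coeffs, basis_dims = nb,
                template_grid = tgrid, converged = start$converged)
}

# Dense native-world coordinates of every template voxel (shape x 3).
forward_field <- function(t) {
  shape <- t$template_grid$shape
  g <- strided_grid(shape, 1L)
  wt <- voxel_to_world(g$coords, t$template_grid$affine)
  if (!is.null(t$coeffs)) {
    D <- coeffs_to_field(t$coeffs, t$basis_dims, shape)
    wt <- wt + cbind(as.vector(D[, , , 1]), as.vector(D[, , , 2]),
                     as.vector(D[, , , 3]))
  }
  wn <- cbind(wt, 1) %*% t(t$affine[1:3, , drop = FALSE])
  array(wn, c(shape, 3))
}

#' Spatially normalize a native volume to a template
#'
#' Runs the affine stage then the nonlinear stage, and resamples the source
#' onto the template grid by trilinear interpolation through the estimated
#' transform.
#'
#' @inheritParams estimate_affine
#' @return list with `normalized` (template-space `volume`) and `transform`
#'   (`srr_transform`).
#' @export
spatially_normalize <- function(source, template,
                                params = registration_params()) {
  t_aff <- estimate_affine(source, template, params)
  t_nl <- estimate_nonlinear(source, template, t_aff, params)
  list(normalized = resample_to_template(source, t_nl), transform = t_nl)
}

#' Resample a native volume onto the template grid through a transform
#'
#' @param source native-space `volume`.
#' @param t an `srr_transform`.
#' @return a template-space `volume` on the template grid.
#' @export
resample_to_template <- function(source, t) {
  shape <- t$template_grid$shape
  wn <- forward_field(t)
  n2v <- solve(source$affine)
  wn <- matrix(wn, prod(shape), 3)
  vn <- cbind(wn, 1) %*% t(n2v[1:3, , drop = FALSE])
  vals <- interp3(source$data, vn[, 1], vn[, 2], vn[, 3])
  new_volume(array(vals, shape), voxel_size = t$template_grid$voxel_size,
             affine = t$template_grid$affine, space = "template")
}

#' Invert a spatial-normalization transform
#'
#' The affine factor is inverted in closed form; the deformation is inverted
#' by fixed-point iteration on the displacement field until the composition
#' residual is below `tolerance_voxels` or `max_iter` is reached. The result
#' is a dense map from native voxels to template voxel coordinates together
#' with a residual map.
#'
#' @param t an `srr_transform`.
#' @param native_grid a native `volume` or a grid spec
#'   (`list(shape, voxel_size, affine)`).
#' @param tolerance_voxels convergence tolerance of the composition residual,
#'   in native voxels.
#' @param max_iter iteration cap for the fixed-point loop.
#' @return an object of class `inverse_deformation` with elements `coords`
#'   (array shape x 3 of 0-based template voxel coordinates), `residual`
#'   (array, native voxels), `native_grid`, `template_grid`.
#' @export
invert_transform <- function(t, native_grid, tolerance_voxels = 0.1,
                             max_iter = 50) {
  ng <- grid_spec(native_grid)
  tg <- t$template_grid
  Ainv <- solve(t$affine)
  has_warp <- !is.null(t$coeffs) && any(t$coeffs != 0)
  D <- if (has_warp) coeffs_to_field(t$coeffs, t$basis_dims, tg$shape)
  if (has_warp) {
    # folding check: Jacobian determinant of u + d(u) on the template grid
    jd <- warp_jacobian_det(D, tg$voxel_size)
    frac <- mean(jd <= 0)
    if (frac > 0)
      stop(sprintf(paste0("transform is not invertible: non-positive Jacobian",
                          " on %.2f%% of template voxels"), 100 * frac))
  }
  g <- strided_grid(ng$shape, 1L)
  wn <- voxel_to_world(g$coords, ng$affine)
  q <- cbind(wn, 1) %*% t(Ainv[1:3, , drop = FALSE])
  t_w2v <- solve(tg$affine)
  u <- q
  iters <- 0L
  if (has_warp) {
    Dx <- D[, , , 1]; Dy <- D[, , , 2]; Dz <- D[, , , 3]
    active <- seq_len(nrow(u))
    for (k in seq_len(max_iter)) {
      iters <- k
      ua <- u[active, , drop = FALSE]
      tv <- cbind(ua, 1) %*% t(t_w2v[1:3, , drop = FALSE])
      du <- cbind(interp3(Dx, tv[, 1], tv[, 2], tv[, 3]),
                  interp3(Dy, tv[, 1], tv[, 2], tv[, 3]),
                  interp3(Dz, tv[, 1], tv[, 2], tv[, 3]))
      u_new <- q[active, , drop = FALSE] - du
      step <- apply(abs(u_new - ua), 1, max) / min(ng$voxel_size)
      u[active, ] <- u_new
      active <- active[step >= tolerance_voxels / 10]
      if (length(active) == 0) break
    }
  }
  # composition residual in native voxel units
  tv <- cbind(u, 1) %*% t(t_w2v[1:3, , drop = FALSE])
  if (has_warp) {
    du <- cbind(interp3(D[, , , 1], tv[, 1], tv[, 2], tv[, 3]),
                interp3(D[, , , 2], tv[, 1], tv[, 2], tv[, 3]),
                interp3(D[, , , 3], tv[, 1], tv[, 2], tv[, 3]))
  } else du <- 0
  w_back <- cbind(u + du, 1) %*% t(t$affine[1:3, , drop = FALSE])
  res_mm <- sqrt(rowSums((w_back - wn)^2))
  residual <- array(res_mm / min(ng$voxel_size), ng$shape)
  structure(list(coords = array(tv, c(ng$shape, 3)),
                 residual = residual,
                 tolerance_voxels = tolerance_voxels,
                 iterations = iters,
                 native_grid = ng, template_grid = tg),
            class = "inverse_deformation")
}

# Jacobian determinant of x + d(x) by central differences (d in mm on the
# template grid with given voxel size).
warp_jacobian_det <- function(D, voxel_size) {
  d <- dim(D)[1:3]
  J <- array(0, c(d, 3, 3))
  for (c in 1:3) {
    g <- gradient_arrays(D[, , , c])
    for (ax in 1:3) J[, , , c, ax] <- g[[ax]] / voxel_size[ax]
  }
  for (ax in 1:3) J[, , , ax, ax] <- J[, , , ax, ax] + 1
  J[, , , 1, 1] * (J[, , , 2, 2] * J[, , , 3, 3] - J[, , , 2, 3] * J[, , , 3, 2]) -
  J[, , , 1, 2] * (J[, , , 2, 1] * J[, , , 3, 3] - J[, , , 2, 3] * J[, , , 3, 1]) +
  J[, , , 1, 3] * (J[, , , 2, 1] * J[, , , 3, 2] - J[, , , 2, 2] * J[, , , 3, 1])
}

#' Map a template-space VOI into native space
#'
#' For every native voxel the template-space mask is evaluated at the
#' inverse-mapped position by trilinear interpolation of the 0/1 mask, and
#' the voxel is included when the interpolated value is at least 0.5.
#'
#' @param voi a template-space `voi_mask`.
#' @param inv an [invert_transform()] result defined on the target native grid.
#' @return a native-space `voi_mask` with the same role.
#' @export
map_voi_to_native <- function(voi, inv) {
  stopifnot(inherits(voi, "voi_mask"), inherits(inv, "inverse_deformation"))
  if (voi$space != "template") stop("voi must be in template space")
  if (!all(dim(voi$data) == inv$template_grid$shape))
    stop("voi grid does not match the transform's template grid")
  tv <- matrix(inv$coords, prod(inv$native_grid$shape), 3)
  vals <- interp3(voi$data, tv[, 1], tv[, 2], tv[, 3])
  m <- array(as.numeric(vals >= 0.5), inv$native_grid$shape)
  if (sum(m) < 1)
    stop("inverse-mapped VOI (", voi$role, ") is empty on the native grid")
  new_voi_mask(m, role = voi$role, voxel_size = inv$native_grid$voxel_size,
               affine = inv$native_grid$affine, space = "native")
}

#' Serialize a transform to YAML
#'
#' Stores the affine, the deformation coefficients, and the template grid in
#' a plain-text YAML file; the roundtrip is lossless to full double precision.
#'
#' @param t an `srr_transform`.
#' @param path output `.yaml` path.
#' @return the path, invisibly.
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "srr_transform"))
  obj <- list(
    affine = apply(t$affine, 1, function(r) sprintf("%.17g", r), simplify = FALSE),
    basis_dims = as.integer(t$basis_dims),
    coeffs = if (!is.null(t$coeffs)) sprintf("%.17g", as.vector(t$coeffs)),
    template_grid = list(shape = as.integer(t$template_grid$shape),
                         voxel_size = sprintf("%.17g", t$template_grid$voxel_size),
                         affine = apply(t$template_grid$affine, 1,
                                        function(r) sprintf("%.17g", r),
                                        simplify = FALSE)),
    converged = isTRUE(t$converged))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a serialized transform
#'
#' @param path a YAML file written by [write_transform()].
#' @return an `srr_transform`.
#' @export
read_transform <- function(path) {
  obj <- yaml::read_yaml(path)
  aff <- t(sapply(obj$affine, as.numeric))
  tg <- list(shape = as.integer(obj$template_grid$shape),
             voxel_size = as.numeric(obj$template_grid$voxel_size),
             affine = t(sapply(obj$template_grid$affine, as.numeric)))
  coeffs <- NULL
  if (!is.null(obj$coeffs))
    coeffs <- matrix(as.numeric(obj$coeffs), ncol = 3)
  new_transform(affine = aff, coeffs = coeffs,
                basis_dims = if (!is.null(obj$basis_dims)) as.integer(obj$basis_dims),
                template_grid = tg, converged = isTRUE(obj$converged))
}
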