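# Spatial normalization, transform inversion, and VOI transfer.

tpl_small <- function() fixture("tpl_small", function() {
  v <- make_phantom(small_spec(psf_fwhm_mm = 8))$volume
  v$space <- "template"
  v
})

# full-resolution (2.9 mm) template for gradient-sensitive recovery checks
tpl_full <- function() fixture("tpl_full", function() {
  v <- make_phantom(phantom_spec(psf_fwhm_mm = 8, noise_model = "none"))$volume
  v$space <- "template"
  v
})

test_that("registration parameter validation", {
  expect_error(registration_params(nonlinear_iterations = 0), ">= 1")
  expect_error(registration_params(regularization_weight = -1), ">= 0")
  expect_error(registration_params(affine_dof = 6), "12")
})

test_that("self-registration recovers the identity affine", {
  tpl <- tpl_small()
  t <- estimate_affine(tpl, tpl, registration_params(source_smoothing_fwhm_mm = 0))
  # identity to within 0.1 voxel anywhere in the field of view
  g <- expand.grid(x = c(-90, 0, 90), y = c(-90, 0, 90), z = c(-90, 0, 90))
  moved <- cbind(as.matrix(g), 1) %*% t(t$affine[1:3, ])
  expect_lt(max(abs(moved - as.matrix(g))), 0.1 * 5.8)
})

test_that("known translations and rotations are recovered", {
  tpl <- tpl_full()
  # exactly 2 voxels along x
  src_t <- make_phantom(phantom_spec(psf_fwhm_mm = 8, noise_model = "none",
                                     pose = c(5.8, 0, 0, rep(0, 9))))$volume
  ta <- estimate_affine(src_t, tpl)
  expect_lt(max(abs(ta$affine[1:3, 4] - c(5.8, 0, 0))) / 2.9, 0.2)

  # 5 degrees in-plane
  src_r <- make_phantom(phantom_spec(psf_fwhm_mm = 8, noise_model = "none",
                                     pose = c(0, 0, 0, 0, 0, 5,
                                              rep(0, 6))))$volume
  tr <- estimate_affine(src_r, tpl)
  ang <- atan2(tr$affine[2, 1], tr$affine[1, 1]) * 180 / pi
  expect_lt(abs(ang - 5), 0.5)
})

test_that("degenerate constant images are rejected", {
  flat <- new_volume(array(1, c(16, 16, 16)))
  expect_error(estimate_affine(flat, flat, registration_params()), "degenerate")
})

test_that("nonlinear self-registration leaves a near-zero deformation", {
  tpl <- tpl_small()
  p <- registration_params(source_smoothing_fwhm_mm = 0)
  t <- estimate_nonlinear(tpl, tpl, estimate_affine(tpl, tpl, p), p)
  D <- striatr:::coeffs_to_field(t$coeffs, t$basis_dims, t$template_grid$shape)
  expect_lt(sum(D^2), 1e-3 * sum(tpl$data^2))
})

test_that("a known smooth warp is substantially removed and regularization is monotone", {
  tpl <- tpl_full()
  src <- make_phantom(phantom_spec(psf_fwhm_mm = 8, noise_model = "none",
                                   warp_amplitude_mm = 4))$volume
  p <- registration_params()
  ta <- estimate_affine(src, tpl, p)
  ssd_of <- function(t) sum((resample_to_template(src, t)$data - tpl$data)^2)
  ssd_before <- ssd_of(ta)
  tn <- estimate_nonlinear(src, tpl, ta, p)
  expect_lt(ssd_of(tn) / ssd_before, 0.20)
  # doubling the regularization does not increase the bending energy
  bending <- function(t) {
    fov <- t$template_grid$shape * t$template_grid$voxel_size
    om <- function(k, L) (pi * seq(0, k - 1) / L)^2
    w2 <- outer(outer(om(t$basis_dims[1], fov[1]), om(t$basis_dims[2], fov[2]),
                      "+"), om(t$basis_dims[3], fov[3]), "+")
    sum(sweep(t$coeffs^2, 1, as.vector(w2^2), `*`))
  }
  t2 <- estimate_nonlinear(src, tpl, ta,
                           registration_params(regularization_weight = 2))
  expect_lte(bending(t2), bending(tn) + 1e-12)
})

test_that("spatially_normalize improves template correlation and serializes losslessly", {
  tpl <- tpl_small()
  src0 <- make_phantom(small_spec(psf_fwhm_mm = 8))$volume
  n0 <- spatially_normalize(src0, tpl)
  expect_gt(cor(as.vector(n0$normalized$data), as.vector(tpl$data)), 0.99)

  src <- make_phantom(small_spec(psf_fwhm_mm = 8,
                                 pose = c(5, -3, 2, 0, 0, 5, rep(0, 6)),
                                 warp_amplitude_mm = 3))$volume
  pre <- cor(as.vector(src$data), as.vector(tpl$data))
  n1 <- spatially_normalize(src, tpl)
  post <- cor(as.vector(n1$normalized$data), as.vector(tpl$data))
  expect_gt(post, pre)

  dir <- withr::local_tempdir()
  f <- file.path(dir, "transform.yaml")
  write_transform(n1$transform, f)
  t2 <- read_transform(f)
  expect_equal(t2$affine, n1$transform$affine, tolerance = 0)
  expect_equal(t2$coeffs, n1$transform$coeffs, tolerance = 0)
  expect_lt(max(abs(resample_to_template(src, t2)$data - n1$normalized$data)),
            1e-6)
})

test_that("affine-only transforms invert to machine precision", {
  tpl <- tpl_small()
  A <- striatr:::pose_matrix(c(4, -6, 2, 3, -2, 4, 0.05, -0.03, 0.02, 0, 0, 0))
  t <- striatr:::new_transform(A, template_grid = striatr:::grid_spec(tpl))
  expect_lt(max(abs(A %*% solve(A) - diag(4))), 1e-10)
  inv <- invert_transform(t, tpl)
  expect_lt(max(inv$residual), 1e-8)
  # inverse coordinates equal the closed-form affine inverse
  g <- striatr:::strided_grid(dim(tpl$data), 1L)
  w <- striatr:::voxel_to_world(g$coords, tpl$affine)
  u <- cbind(w, 1) %*% t(solve(A)[1:3, ])
  tv <- cbind(u, 1) %*% t(solve(tpl$affine)[1:3, ])
  expect_lt(max(abs(matrix(inv$coords, ncol = 3) - tv)), 1e-8)
})

test_that("identity transform inverts to the identity with zero residual", {
  tpl <- tpl_small()
  t <- striatr:::new_transform(diag(4), template_grid = striatr:::grid_spec(tpl))
  inv <- invert_transform(t, tpl)
  expect_equal(max(inv$residual), 0)
  g <- striatr:::strided_grid(dim(tpl$data), 1L)
  expect_lt(max(abs(matrix(inv$coords, ncol = 3) - g$coords)), 1e-10)
})

test_that("smooth warps invert with sub-tolerance roundtrip residual in the brain", {
  tpl <- tpl_small()
  src <- make_phantom(small_spec(psf_fwhm_mm = 8, warp_amplitude_mm = 4,
                                 pose = c(3, -2, 1, 0, 0, 3, rep(0, 6))))$volume
  t <- spatially_normalize(src, tpl)$transform
  inv <- invert_transform(t, src, tolerance_voxels = 0.1)
  brain <- make_phantom(small_spec(psf_fwhm_mm = 8, warp_amplitude_mm = 4,
                                   pose = c(3, -2, 1, 0, 0, 3,
                                            rep(0, 6))))$masks_native$brain > 0
  expect_lt(quantile(inv$residual[brain], 0.99), 0.2)
})

test_that("map_voi_to_native is exact for identity and integer translations", {
  bundle <- small_bundle()
  tpl <- bundle$template
  tg <- striatr:::grid_spec(tpl)
  t_id <- striatr:::new_transform(diag(4), template_grid = tg)
  inv_id <- invert_transform(t_id, tpl)
  out <- map_voi_to_native(bundle$striatum_left, inv_id)
  expect_identical(out$data, bundle$striatum_left$data)
  expect_identical(out$role, "striatum_left")
  expect_identical(out$space, "native")

  # one-voxel translation: output equals the shifted input exactly
  A <- diag(4); A[1, 4] <- 5.8
  inv_t <- invert_transform(striatr:::new_transform(A, template_grid = tg), tpl)
  out_t <- map_voi_to_native(bundle$striatum_left, inv_t)
  shifted <- array(0, dim(bundle$striatum_left$data))
  shifted[2:32, , ] <- bundle$striatum_left$data[1:31, , ]
  expect_identical(out_t$data, shifted)
})

test_that("uniform scaling changes mapped VOI volume by the Jacobian", {
  tpl <- tpl_small()
  tg <- striatr:::grid_spec(tpl)
  ball <- array(0, dim(tpl$data))
  g <- striatr:::strided_grid(dim(tpl$data), 1L)
  w <- striatr:::voxel_to_world(g$coords, tpl$affine)
  ball[rowSums(w^2) <= 50^2] <- 1
  voi <- new_voi_mask(ball, role = "reference", voxel_size = tpl$voxel_size,
                      affine = tpl$affine, space = "template")
  s <- 1.2
  A <- diag(c(s, s, s, 1))   # template world -> native world scaling
  inv <- invert_transform(striatr:::new_transform(A, template_grid = tg), tpl)
  out <- map_voi_to_native(voi, inv)
  expect_lt(abs(sum(out$data) / (sum(voi$data) * s^3) - 1), 0.05)
})

test_that("folding transforms are rejected by the inversion", {
  tpl <- tpl_small()
  tg <- striatr:::grid_spec(tpl)
  nb <- striatr:::basis_size(tg$shape, tg$voxel_size, 60)
  coeffs <- matrix(0, prod(nb), 3)
  coeffs[2, 1] <- 20000  # enormous low-frequency x-displacement folds space
  t_bad <- striatr:::new_transform(diag(4), coeffs = coeffs, basis_dims = nb,
                                   template_grid = tg)
  expect_error(invert_transform(t_bad, tpl), "not invertible")
})
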