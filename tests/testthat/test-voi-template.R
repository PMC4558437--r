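# Normal-template construction and template-space VOI definition.

test_that("averaging identical aligned controls reproduces the input", {
  ph <- make_phantom(small_spec(psf_fwhm_mm = 8))
  ref <- ph$volume; ref$space <- "template"
  # normalize the control to unit brain mean so the scaling step is neutral
  brain <- ref$data > 0.05 * max(ref$data)
  ctrl <- ref; ctrl$data <- ctrl$data / mean(ctrl$data[brain]); ctrl$space <- "native"
  tpl <- build_normal_template(list(ctrl, ctrl), ref,
                               registration_params(source_smoothing_fwhm_mm = 0))
  expect_lt(max(abs(tpl$data - ctrl$data)), 1e-6)
})

test_that("aligned constants average without the scaling step", {
  ref <- new_volume(array(1, c(16, 16, 16)))
  a <- new_volume(array(1, c(16, 16, 16)))
  b <- new_volume(array(3, c(16, 16, 16)))
  tpl <- build_normal_template(list(a, b), ref, scale = FALSE, register = FALSE)
  expect_true(all(tpl$data == 2))
  expect_error(build_normal_template(list(a), ref), "at least 2")
})

test_that("template from randomly posed controls beats every misaligned input", {
  truth <- make_phantom(small_spec(psf_fwhm_mm = 8))$volume
  ref <- truth; ref$space <- "template"
  poses <- list(c(4, -2, 3, 2, 0, -3, rep(0, 6)),
                c(-3, 5, -2, -2, 3, 2, rep(0, 6)),
                c(2, 2, -4, 3, -2, 0, rep(0, 6)),
                c(-5, -3, 1, 0, 2, 3, rep(0, 6)))
  controls <- lapply(poses, function(p)
    make_phantom(small_spec(psf_fwhm_mm = 8, pose = p))$volume)
  tpl <- build_normal_template(controls, ref, scale = FALSE)
  cor_tpl <- cor(as.vector(tpl$data), as.vector(truth$data))
  cor_inputs <- vapply(controls, function(v)
    cor(as.vector(v$data), as.vector(truth$data)), 0)
  expect_gte(cor_tpl, max(cor_inputs))
})

test_that("60%-of-max threshold yields one striatal VOI per side", {
  v <- new_volume(array(0, c(24, 24, 24)), voxel_size = c(4, 4, 4))
  v$data[5:8, 10:14, 10:14] <- 10     # left blob (negative world x)
  v$data[17:20, 10:14, 10:14] <- 8    # right blob, still above 6.0
  v$data[11:14, 4:6, 10:12] <- 5      # sub-threshold distractor
  vois <- define_striatal_vois(v, 0.6)
  expect_equal(sum(vois$striatum_left$data), 100)
  expect_equal(sum(vois$striatum_right$data), 100)
  expect_true(all(which(vois$striatum_left$data == 1, arr.ind = TRUE)[, 1] <= 8))
  # relative threshold: global intensity scaling changes nothing
  v2 <- v; v2$data <- v$data * 37.5
  vois2 <- define_striatal_vois(v2, 0.6)
  expect_identical(vois2$striatum_left$data, vois$striatum_left$data)
  # voxel count is non-increasing in the threshold fraction (0.9 would leave
  # only the brighter blob, which is rejected as one-sided)
  counts <- vapply(c(0.3, 0.5, 0.7), function(th)
    sum(define_striatal_vois(v, th)$striatum_left$data), 0)
  expect_true(all(diff(counts) <= 0))
  expect_error(define_striatal_vois(v, 0.9), "one side")
  # degenerate inputs
  expect_error(define_striatal_vois(new_volume(array(1, c(16, 16, 16))), 0.6),
               "degenerate")
  expect_error(define_striatal_vois(v, 1.2), "between 0 and 1")
})

test_that("a single midline-spanning component is split at the mid-sagittal plane", {
  v <- new_volume(array(0, c(24, 24, 24)), voxel_size = c(4, 4, 4))
  v$data[9:16, 10:14, 10:14] <- 10   # spans the x = 0 plane (between 12 and 13)
  vois <- define_striatal_vois(v, 0.6)
  expect_equal(sum(vois$striatum_left$data) + sum(vois$striatum_right$data),
               8 * 5 * 5)
  expect_true(all(which(vois$striatum_left$data == 1, arr.ind = TRUE)[, 1] <= 12))
  expect_true(all(which(vois$striatum_right$data == 1, arr.ind = TRUE)[, 1] >= 13))
})

test_that("template-derived striatal VOIs overlap the generator ground truth", {
  bundle <- mid_bundle()
  truth <- make_phantom(mid_spec())$masks_template
  expect_gte(dice_coefficient(bundle$striatum_left$data,
                              truth$striatum_left$data), 0.7)
  expect_gte(dice_coefficient(bundle$striatum_right$data,
                              truth$striatum_right$data), 0.7)
})

test_that("reference VOI respects labels, slice range, and striatal exclusion", {
  ph <- make_phantom(small_spec())
  tpl <- ph$volume; tpl$space <- "template"
  labels <- new_volume(ph$masks_template$reference$data,
                       voxel_size = tpl$voxel_size, affine = tpl$affine,
                       space = "template")
  vois <- define_striatal_vois(tpl, 0.6)
  full <- define_reference_voi(labels, 1, striatal = vois)
  expect_equal(sum(full$data * vois$striatum_left$data), 0)
  # ribbon minus striatal overlap (ground-truth ribbon excludes striata already)
  expect_equal(sum(full$data), sum(ph$masks_template$reference$data))
  # restricting the slice range never grows the mask
  ranges <- list(c(1, 32), c(8, 24), c(12, 20), c(14, 16))
  counts <- vapply(ranges, function(r)
    sum(define_reference_voi(labels, 1, slice_range = r)$data), 0)
  expect_true(all(diff(counts) <= 0))
  expect_error(define_reference_voi(labels, 1, slice_range = c(10, 9)),
               "zero slices")
  expect_error(define_reference_voi(labels, 99), "empty")
})

test_that("template bundles enforce disjointness and survive disk roundtrips", {
  bundle <- small_bundle()
  expect_error(template_bundle(bundle$template, bundle$striatum_left,
                               bundle$striatum_left, bundle$reference),
               "overlap")
  bad_ref <- new_voi_mask(bundle$striatum_right$data, role = "reference",
                          voxel_size = bundle$template$voxel_size,
                          affine = bundle$template$affine, space = "template")
  expect_error(template_bundle(bundle$template, bundle$striatum_left,
                               bundle$striatum_right, bad_ref),
               "intersect")
  dir <- withr::local_tempdir()
  save_template_bundle(bundle, file.path(dir, "bundle"))
  b2 <- load_template_bundle(file.path(dir, "bundle"))
  expect_identical(b2$striatum_left$data, bundle$striatum_left$data)
  expect_identical(b2$reference$data, bundle$reference$data)
  expect_equal(b2$template$data, bundle$template$data, tolerance = 1e-12)
})
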