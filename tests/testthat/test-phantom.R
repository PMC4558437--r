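# Digital phantom generator and statistical cohort simulators.

test_that("noiseless unblurred phantom has the exact requested contrast", {
  ph <- make_phantom(small_spec(contrast = c(2, 2)))
  r <- mean_in_mask(ph$volume, ph$masks_native$striatum_left) /
       mean_in_mask(ph$volume, ph$masks_native$reference)
  expect_equal(r, 2)
  rr <- mean_in_mask(ph$volume, ph$masks_native$striatum_right) /
        mean_in_mask(ph$volume, ph$masks_native$reference)
  expect_equal(rr, 2)
})

test_that("PSF blur drags the measured ratio toward 1, monotonically", {
  ratios <- vapply(c(0, 6, 12, 18), function(fwhm) {
    ph <- make_phantom(small_spec(psf_fwhm_mm = fwhm, contrast = c(2, 2)))
    mean_in_mask(ph$volume, ph$masks_native$striatum_left) /
      mean_in_mask(ph$volume, ph$masks_native$reference)
  }, 0)
  expect_equal(ratios[1], 2)
  expect_true(all(diff(ratios) < 0))
  expect_true(all(ratios > 1))
})

test_that("phantoms are deterministic under a fixed seed", {
  sp <- phantom_spec(grid_shape = c(32, 32, 32), voxel_size = rep(5.8, 3),
                     noise_model = "gaussian", noise_level = 0.05, seed = 42)
  expect_identical(make_phantom(sp)$volume$data, make_phantom(sp)$volume$data)
  sp2 <- sp; sp2$seed <- 43L
  expect_false(identical(make_phantom(sp)$volume$data,
                         make_phantom(sp2)$volume$data))
})

test_that("phantom spec validation catches impossible geometry", {
  expect_error(small_spec(striatal_centers = rbind(c(-55, 0, 0), c(20, 8, 2))),
               "outside the brain")
  expect_error(phantom_spec(grid_shape = c(4, 4, 4)), "grid too small")
  expect_error(small_spec(contrast = c(-1, 2)), "contrast")
  expect_error(small_spec(psf_fwhm_mm = -2), "psf")
})

test_that("pose and warp move the native anatomy but not the template masks", {
  ph0 <- make_phantom(small_spec())
  php <- make_phantom(small_spec(pose = c(11.6, 0, 0, rep(0, 9))))
  expect_identical(php$masks_template$striatum_left$data,
                   ph0$masks_template$striatum_left$data)
  # 2-voxel translation along +x: native mask is the template mask shifted
  shifted <- array(0, dim(ph0$masks_template$striatum_left$data))
  shifted[3:32, , ] <- ph0$masks_template$striatum_left$data[1:30, , ]
  expect_identical(php$masks_native$striatum_left$data, shifted)
})

test_that("draw_srr_cohort reproduces subgroup statistics and pooled means", {
  cs <- cohort_spec(seed = 11)
  coh <- draw_srr_cohort(cs)
  expect_equal(nrow(coh), sum(cs$subgroups$n))
  expect_identical(as.integer(table(coh$group)[c("PD", "HC", "ET")]),
                   c(365L, 28L, 33L))
  # degenerate draw: sd 0 gives the subgroup mean exactly
  sg0 <- cs$subgroups; sg0$sd_srr <- 0
  coh0 <- draw_srr_cohort(cohort_spec(sg0, seed = 1))
  for (lab in sg0$label)
    expect_true(all(coh0$srr_true[coh0$subgroup == lab] ==
                      sg0$mean_srr[sg0$label == lab]))
  # determinism + seed separation
  expect_identical(draw_srr_cohort(cs), coh)
  expect_false(identical(draw_srr_cohort(cohort_spec(seed = 12)), coh))
  # durations lie in the subgroup ranges; non-PD have none
  pd <- coh[coh$group == "PD", ]
  expect_true(all(pd$duration_years >= 0 & pd$duration_years <= 33))
  expect_true(all(is.na(coh$duration_years[coh$group != "PD"])))
  # empirical subgroup means converge (3 SE) on a large replicate
  big <- cs$subgroups; big$n <- big$n * 20
  cohb <- draw_srr_cohort(cohort_spec(big, seed = 5))
  for (i in seq_len(nrow(big))) {
    v <- cohb$srr_true[cohb$subgroup == big$label[i]]
    se <- big$sd_srr[i] / sqrt(big$n[i])
    expect_lt(abs(mean(v) - big$mean_srr[i]), 3 * se + 1e-12)
  }
})

test_that("printed subgroup sizes and means pool to the printed group means", {
  sg <- cohort_spec()$subgroups
  pd <- sg$group == "PD"
  expect_equal(round(sum(sg$n[pd] * sg$mean_srr[pd]) / sum(sg$n[pd]), 2), 1.47)
  npd <- !pd
  expect_equal(round(sum(sg$n[npd] * sg$mean_srr[npd]) / sum(sg$n[npd]), 2), 1.95)
})

test_that("make_cohort_images sets true contrast from the drawn SRR with independent poses", {
  sg <- data.frame(label = "PD_le2", group = "PD", n = 4L, mean_srr = 1.6,
                   sd_srr = 0, duration_min = 0, duration_max = 2)
  base <- small_spec()
  imgs <- make_cohort_images(cohort_spec(sg, seed = 3), base)
  expect_length(imgs, 4)
  poses <- t(vapply(imgs, function(s) s$pose_matrix[1:3, 4], numeric(3)))
  expect_gt(max(dist(poses)), 0)  # poses differ between subjects
  for (s in imgs) {
    expect_equal(s$record$srr_true, 1.6)
    r <- mean_in_mask(s$volume, s$masks_native$striatum_left) /
         mean_in_mask(s$volume, s$masks_native$reference)
    expect_equal(r, 1.6, tolerance = 1e-12)
  }
  # different cohort seed gives a different pose sequence
  imgs2 <- make_cohort_images(cohort_spec(sg, seed = 4), base)
  expect_false(identical(imgs[[1]]$pose_matrix, imgs2[[1]]$pose_matrix))
})

test_that("simulate_duration_cohort follows the generating quadratic", {
  m <- quadratic_model(0.0011, -0.0273, 1.572)
  coh0 <- simulate_duration_cohort(m, per_year_n = rep(5, 10), noise_sd = 0,
                                   seed = 2)
  for (x in 1:10) {
    v <- coh0$srr[coh0$duration_years > x - 1 & coh0$duration_years <= x]
    expect_true(all(abs(v - predict_srr(m, x)) < 1e-12))
  }
  # year-0 limit of the printed model is its intercept
  expect_equal(predict_srr(m, 0), 1.572)
  # CLT check: per-year sample means near the curve at large n
  cohn <- simulate_duration_cohort(m, per_year_n = rep(400, 8),
                                   noise_sd = 0.17, seed = 9)
  for (x in 1:8) {
    v <- cohn$srr[ceiling(cohn$duration_years) == x]
    expect_lt(abs(mean(v) - predict_srr(m, x)), 3 * 0.17 / sqrt(length(v)))
  }
})
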