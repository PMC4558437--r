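# Shared fixtures. Phantoms and template bundles are memoised so that
# registration-heavy objects are built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_env))
    assign(name, make(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# Small grid (32^3, 5.8 mm voxels) keeps the 185.6 mm field of view of the
# default phantom; used for transform-level tests.
small_spec <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(32, 32, 32), voxel_size = rep(5.8, 3),
         psf_fwhm_mm = 0, noise_model = "none"),
    list(...))
  do.call(phantom_spec, args)
}

# Mid grid (48^3, ~3.87 mm voxels), same field of view; used for end-to-end
# SRR tests where mask resolution matters.
mid_spec <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(48, 48, 48), voxel_size = rep(185.6 / 48, 3),
         psf_fwhm_mm = 0, noise_model = "none"),
    list(...))
  do.call(phantom_spec, args)
}

# Template bundle derived from a noiseless, unposed phantom: the phantom
# volume acts as template, striatal VOIs come from the 60% threshold, and the
# reference VOI from the ground-truth cortical ribbon labels.
bundle_from_phantom <- function(spec) {
  ph <- make_phantom(spec)
  template <- ph$volume
  template$space <- "template"
  striatal <- define_striatal_vois(template, 0.6)
  labels <- new_volume(ph$masks_template$reference$data,
                       voxel_size = template$voxel_size,
                       affine = template$affine, space = "template")
  reference <- define_reference_voi(labels, 1, striatal = striatal)
  template_bundle(template, striatal$striatum_left, striatal$striatum_right,
                  reference)
}

small_bundle <- function() fixture("small_bundle",
                                   function() bundle_from_phantom(small_spec()))
mid_bundle <- function() fixture("mid_bundle",
                                 function() bundle_from_phantom(mid_spec()))

dice_coefficient <- function(a, b) 2 * sum(a * b) / (sum(a) + sum(b))

# Registration settings for sharp (psf = 0) synthetic templates: the clinical
# workflow leaves the template unsmoothed because it is already smooth (an
# average of reconstructed scans); a piecewise-constant phantom template
# violates that assumption, so it is smoothed to match the source smoothing.
sharp_template_params <- function()
  registration_params(template_smoothing_fwhm_mm = 8)

# Brute-force AUC oracle: exhaustive pair count with tie credit, i.e.
# P(control > diseased) + 0.5 P(tie).
auc_pair_oracle <- function(diseased, control) {
  s <- 0
  for (d in diseased) for (cc in control)
    s <- s + (cc > d) + 0.5 * (cc == d)
  s / (length(diseased) * length(control))
}
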