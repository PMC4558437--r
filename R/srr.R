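# Striatal-to-reference ratio computation: inverse-VOI and conventional
# pipelines.

#' Compute the striatal-to-reference ratio
#'
#' SRR = mean striatal intensity / mean reference intensity. Striatal mask
#' selection follows the contralateral rule: symptoms on the left use the
#' right striatum and vice versa; bilateral symptoms (or no symptomatic side,
#' as in non-PD subjects) use the union of both striata.
#'
#' @param native a `volume` (native or normalized space).
#' @param striatum_left,striatum_right,reference `voi_mask`s on the same grid
#'   as `native`.
#' @param side symptomatic side: `"left"`, `"right"`, `"bilateral"`, `"none"`.
#' @return the SRR as a single positive number.
#' @export
compute_srr <- function(native, striatum_left, striatum_right, reference,
                        side = c("bilateral", "left", "right", "none")) {
  side <- match.arg(side)
  striatum <- switch(side,
    left = striatum_right,      # contralateral
    right = striatum_left,
    bilateral = ,
    none = {
      u <- array(as.numeric(striatum_left$data + striatum_right$data > 0),
                 dim(striatum_left$data))
      new_voi_mask(u, role = "striatum_bilateral",
                   voxel_size = striatum_left$voxel_size,
                   affine = striatum_left$affine,
                   space = striatum_left$space)
    })
  ref_mean <- mean_in_mask(native, reference)
  if (ref_mean <= 0) stop("non-positive mean in the reference VOI")
  mean_in_mask(native, striatum) / ref_mean
}

#' Specific uptake ratio from SRR
#'
#' The specific uptake ratio (SUR) is the same biomarker expressed as
#' specific binding: SUR = SRR - 1.
#'
#' @param srr numeric SRR value(s).
#' @return SUR value(s).
#' @export
srr_to_sur <- function(srr) srr - 1

#' Quantify one subject with the inverse-VOI pipeline
#'
#' The subject's native volume is spatially normalized to the bundle's
#' template, the transform is inverted, the template-space striatal and
#' reference VOIs are carried back onto the native grid, and the SRR is
#' computed on the ORIGINAL (untouched) native image.
#'
#' @param native native-space `volume`.
#' @param bundle a [template_bundle()].
#' @param side symptomatic side (see [compute_srr()]).
#' @param params a [registration_params()].
#' @param audit_dir if non-NULL, the transform and inverse-mapped native
#'   masks are written there for visual confirmation.
#' @param id subject identifier used in audit filenames.
#' @return list with `srr`, `method = "inverse_voi"`, `transform`,
#'   `native_masks`.
#' @export
run_subject_pipeline <- function(native, bundle, side = "bilateral",
                                 params = registration_params(),
                                 audit_dir = NULL, id = "subject") {
  stopifnot(inherits(bundle, "template_bundle"))
  norm <- spatially_normalize(native, bundle$template, params)
  inv <- invert_transform(norm$transform, native)
  masks <- list(
    striatum_left = map_voi_to_native(bundle$striatum_left, inv),
    striatum_right = map_voi_to_native(bundle$striatum_right, inv),
    reference = map_voi_to_native(bundle$reference, inv))
  srr <- compute_srr(native, masks$striatum_left, masks$striatum_right,
                     masks$reference, side = side)
  if (!is.null(audit_dir)) {
    dir.create(audit_dir, showWarnings = FALSE, recursive = TRUE)
    write_transform(norm$transform,
                    file.path(audit_dir, paste0(id, "_transform.yaml")))
    for (nm in names(masks))
      write_volume(masks[[nm]],
                   file.path(audit_dir, paste0(id, "_", nm, "_native.nii.gz")))
  }
  list(srr = srr, method = "inverse_voi", transform = norm$transform,
       native_masks = masks)
}

#' Quantify one subject with the conventional pipeline
#'
#' The native volume is spatially normalized and the SRR is computed on the
#' NORMALIZED image using the template-space VOIs directly.
#'
#' @inheritParams run_subject_pipeline
#' @return list with `srr`, `method = "conventional"`, `transform`,
#'   `normalized`.
#' @export
run_conventional_pipeline <- function(native, bundle, side = "bilateral",
                                      params = registration_params()) {
  stopifnot(inherits(bundle, "template_bundle"))
  norm <- spatially_normalize(native, bundle$template, params)
  srr <- compute_srr(norm$normalized, bundle$striatum_left,
                     bundle$striatum_right, bundle$reference, side = side)
  list(srr = srr, method = "conventional", transform = norm$transform,
       normalized = norm$normalized)
}
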