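# Normal-template construction and template-space VOI definition.

#' Build the normal template from control volumes
#'
#' Each control volume is spatially normalized to the registration reference
#' (which must already live in template space and contain a scalp shell, as
#' TRODAT scans show scalp uptake), optionally intensity-scaled to unit mean
#' within the reference brain mask, and the voxel-wise arithmetic mean over
#' controls is returned on the template grid.
#'
#' @param controls list of at least two native-space `volume`s.
#' @param reference template-space `volume` used as registration target.
#' @param params a [registration_params()].
#' @param scale if `TRUE` (default) each normalized control is divided by its
#'   mean intensity within the reference brain mask before averaging.
#' @param brain_threshold fraction of the reference maximum defining the brain
#'   mask used for intensity scaling.
#' @param register if `FALSE` the controls are assumed to already lie on the
#'   template grid and are averaged without spatial normalization.
#' @return a template-space `volume` with a `provenance` attribute.
#' @export
build_normal_template <- function(controls, reference,
                                  params = registration_params(),
                                  scale = TRUE, brain_threshold = 0.05,
                                  register = TRUE) {
  if (!is.list(controls) || length(controls) < 2)
    stop("at least 2 control volumes are required")
  brain <- reference$data > brain_threshold * max(reference$data)
  acc <- NULL
  for (i in seq_along(controls)) {
    if (register) {
      norm_i <- tryCatch(
        spatially_normalize(controls[[i]], reference, params)$normalized,
        error = function(e)
          stop("registration failed for control ", i, ": ", conditionMessage(e)))
    } else {
      check_congruent(controls[[i]], reference)
      norm_i <- controls[[i]]
    }
    dat <- norm_i$data
    if (scale) {
      m <- mean(dat[brain])
      if (m <= 0) stop("control ", i, " has non-positive mean in the brain mask")
      dat <- dat / m
    }
    acc <- if (is.null(acc)) dat else acc + dat
  }
  out <- new_volume(acc / length(controls),
                    voxel_size = reference$voxel_size,
                    affine = reference$affine, space = "template")
  attr(out, "provenance") <- list(n_controls = length(controls),
                                  scaled = scale, params = unclass(params))
  out
}

# 26-connected component labelling of a logical/0-1 3-D array.
label_components_26 <- function(mask) {
  d <- dim(mask)
  fg <- which(mask > 0)
  labels <- integer(prod(d))
  if (length(fg) == 0) return(list(labels = array(labels, d), n = 0L))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  coord <- arrayInd(fg, d)
  in_fg <- logical(prod(d)); in_fg[fg] <- TRUE
  lab <- 0L
  for (seed in fg) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    queue <- seed
    labels[seed] <- lab
    while (length(queue) > 0) {
      cur <- queue
      queue <- integer(0)
      cc <- arrayInd(cur, d)
      for (o in seq_len(nrow(offs))) {
        nb <- cc + matrix(offs[o, ], nrow(cc), 3, byrow = TRUE)
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
              nb[, 2] >= 1 & nb[, 2] <= d[2] &
              nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
        new <- lin[in_fg[lin] & labels[lin] == 0L]
        if (length(new)) {
          labels[new] <- lab
          queue <- c(queue, new)
        }
      }
      queue <- unique(queue)
    }
  }
  list(labels = array(labels, d), n = lab)
}

#' Define the striatal VOIs from the template
#'
#' Voxels at or above `threshold_fraction` of the template's maximum intensity
#' form the candidate mask; 26-connected components are extracted and the two
#' largest are assigned left/right by the sign of their world-space x
#' centroid. A single component spanning the midline is split at the
#' mid-sagittal (x = 0) plane. Caudate and putamen remain merged per side.
#'
#' @param template a template-space `volume`.
#' @param threshold_fraction fraction of the global maximum, in (0, 1).
#' @return list with `striatum_left` and `striatum_right` `voi_mask`s.
#' @export
define_striatal_vois <- function(template, threshold_fraction = 0.6) {
  stopifnot(inherits(template, "volume"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie strictly between 0 and 1")
  cand <- template$data >= threshold_fraction * max(template$data)
  if (mean(cand) > 0.5)
    stop("degenerate template: supra-threshold set covers most of the volume")
  if (!any(cand)) stop("no supra-threshold structure in the template")
  cc <- label_components_26(cand)
  sizes <- tabulate(cc$labels[cc$labels > 0], nbins = cc$n)
  g <- strided_grid(dim(template$data), 1L)
  wx <- voxel_to_world(g$coords, template$affine)[, 1]
  mask_for <- function(lab) cc$labels == lab
  if (cc$n >= 2) {
    top <- order(sizes, decreasing = TRUE)[1:2]
    m1 <- mask_for(top[1]); m2 <- mask_for(top[2])
    x1 <- mean(wx[m1]); x2 <- mean(wx[m2])
    if (sign(x1) == sign(x2))
      stop("the two largest supra-threshold components are not separable ",
           "by the midline (centroids on the same side)")
    left <- if (x1 < x2) m1 else m2
    right <- if (x1 < x2) m2 else m1
  } else {
    m <- mask_for(1L)
    left <- m & array(wx < 0, dim(m))
    right <- m & array(wx >= 0, dim(m))
    if (!any(left) || !any(right))
      stop("single supra-threshold component lies entirely on one side; ",
           "cannot define bilateral striatal VOIs")
  }
  list(
    striatum_left = new_voi_mask(array(as.numeric(left), dim(left)),
      role = "striatum_left", voxel_size = template$voxel_size,
      affine = template$affine, space = "template"),
    striatum_right = new_voi_mask(array(as.numeric(right), dim(right)),
      role = "striatum_right", voxel_size = template$voxel_size,
      affine = template$affine, space = "template"))
}

#' Define the cortical reference VOI from a label volume
#'
#' The mask is the union of voxels whose integer label belongs to
#' `included_labels`, restricted to an inclusive axial slice range; voxels
#' belonging to either striatal VOI are excluded.
#'
#' @param labels template-space `volume` of integer labels (an atlas, or the
#'   phantom's cortical-ribbon ground truth).
#' @param included_labels integer labels to include.
#' @param slice_range inclusive 1-based axial (3rd axis) index pair.
#' @param striatal optional list with `striatum_left`/`striatum_right` masks
#'   to exclude.
#' @return a `voi_mask` with role `"reference"`.
#' @export
define_reference_voi <- function(labels, included_labels,
                                 slice_range = NULL, striatal = NULL) {
  stopifnot(inherits(labels, "volume"))
  d <- dim(labels$data)
  if (is.null(slice_range)) slice_range <- c(1L, d[3])
  slice_range <- as.integer(slice_range)
  if (slice_range[1] > slice_range[2])
    stop("slice_range covers zero slices")
  if (slice_range[1] < 1 || slice_range[2] > d[3])
    stop("slice_range out of bounds (1..", d[3], ")")
  m <- array(labels$data %in% included_labels, d)
  keep <- array(FALSE, d)
  keep[, , slice_range[1]:slice_range[2]] <- TRUE
  m <- m & keep
  if (!is.null(striatal)) {
    for (s in striatal)
      if (inherits(s, "voi_mask")) m <- m & !(s$data > 0)
  }
  if (!any(m)) stop("reference VOI is empty for the given labels/slice range")
  new_voi_mask(array(as.numeric(m), d), role = "reference",
               voxel_size = labels$voxel_size, affine = labels$affine,
               space = "template")
}

#' Bundle the template and its VOIs
#'
#' Validates that the striatal masks are disjoint from each other and from the
#' reference mask, and that all masks share the template grid.
#'
#' @param template template-space `volume`.
#' @param striatum_left,striatum_right,reference template-space `voi_mask`s.
#' @param provenance optional list recorded alongside.
#' @return an object of class `template_bundle`.
#' @export
template_bundle <- function(template, striatum_left, striatum_right,
                            reference, provenance = list()) {
  for (m in list(striatum_left, striatum_right, reference)) {
    stopifnot(inherits(m, "voi_mask"))
    check_congruent(template, m)
  }
  if (sum(striatum_left$data * striatum_right$data) > 0)
    stop("striatal masks overlap")
  if (sum((striatum_left$data + striatum_right$data) * reference$data) > 0)
    stop("striatal masks intersect the reference mask")
  structure(list(template = template, striatum_left = striatum_left,
                 striatum_right = striatum_right, reference = reference,
                 provenance = provenance),
            class = "template_bundle")
}

#' @export
print.template_bundle <- function(x, ...) {
  cat(sprintf(paste0("<template_bundle> %s grid; striatum L/R %d/%d voxels, ",
                     "reference %d voxels\n"),
              paste(dim(x$template$data), collapse = "x"),
              sum(x$striatum_left$data), sum(x$striatum_right$data),
              sum(x$reference$data)))
  invisible(x)
}

#' Persist a template bundle as four NIfTI files plus provenance YAML
#'
#' @param bundle a [template_bundle()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
save_template_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "template_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(bundle$template, file.path(dir, "template.nii.gz"))
  write_volume(bundle$striatum_left, file.path(dir, "striatum_left.nii.gz"))
  write_volume(bundle$striatum_right, file.path(dir, "striatum_right.nii.gz"))
  write_volume(bundle$reference, file.path(dir, "reference.nii.gz"))
  yaml::write_yaml(bundle$provenance, file.path(dir, "provenance.yaml"))
  invisible(dir)
}

#' Load a template bundle saved by [save_template_bundle()]
#'
#' @param dir bundle directory.
#' @return a [template_bundle()].
#' @export
load_template_bundle <- function(dir) {
  template <- read_volume(file.path(dir, "template.nii.gz"), space = "template")
  template_bundle(
    template,
    read_voi_mask(file.path(dir, "striatum_left.nii.gz"),
                  role = "striatum_left", space = "template"),
    read_voi_mask(file.path(dir, "striatum_right.nii.gz"),
                  role = "striatum_right", space = "template"),
    read_voi_mask(file.path(dir, "reference.nii.gz"),
                  role = "reference", space = "template"),
    provenance = tryCatch(yaml::read_yaml(file.path(dir, "provenance.yaml")),
                          error = function(e) list()))
}
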