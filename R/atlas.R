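# Atlas construction and the end-to-end segmentation-propagation pipeline:
# keypoints are detected in the unsegmented image and the atlas intensity
# image, described and matched into corresponding-point pairs, which then
# constrain the MI-driven B-spline registration; the atlas labels are
# carried through the recovered transform onto the new image's grid.

#' Atlas: reference-space intensity image plus labels
#'
#' @slot intensity mean intensity Volume in the reference space.
#' @slot labels LabelMap on the same grid.
#' @slot phase time-phase index this atlas represents.
#' @slot provenance identifiers of the contributing images.
#' @export
setClass("Atlas",
  representation(intensity = "Volume", labels = "LabelMap",
                 phase = "integer", provenance = "character"))

setValidity("Atlas", function(object) {
  if (!identical(dim(object@intensity@voxels), dim(object@labels@voxels)))
    return("intensity and labels must share one grid")
  if (max(abs(object@intensity@spacing - object@labels@spacing)) > 1e-9)
    return("intensity and labels must share one grid (spacing)")
  TRUE
})

#' Construct an Atlas
#' @param intensity reference-space Volume.
#' @param labels LabelMap on the same grid.
#' @param phase time-phase index (default 1).
#' @param provenance contributing image identifiers.
#' @export
atlas <- function(intensity, labels, phase = 1L,
                  provenance = character(0)) {
  new("Atlas", intensity = intensity, labels = labels,
      phase = as.integer(phase), provenance = provenance)
}

#' @export
setMethod("show", "Atlas", function(object) {
  cat(sprintf("Atlas (phase %d, %d contributing image(s))\n", object@phase,
              max(1L, length(object@provenance))))
  show(object@intensity)
})

#' Pipeline configuration for segmentation and atlas construction
#'
#' Bundles the detector, matching, metric, optimizer and schedule settings
#' with the penalty weight; every default follows the standard parameter
#' set of the registration framework.
#'
#' @param omega corresponding-point penalty weight (default 0.01).
#' @param t4 descriptor ratio-test threshold (default 0.9).
#' @param harris,dog detector parameter lists (NULL disables a detector).
#' @param mi \code{\link{miSettings}}.
#' @param opt \code{\link{asgdSettings}}.
#' @param sched \code{\link{multiresSchedule}}.
#' @param affineOpt optimizer settings for the affine stage (defaults to
#'   \code{opt}).
#' @export
pipelineSettings <- function(omega = 0.01, t4 = 0.9,
                             harris = harrisParams(), dog = dogParams(),
                             mi = miSettings(), opt = asgdSettings(),
                             sched = multiresSchedule(),
                             affineOpt = opt) {
  list(omega = omega, t4 = t4, harris = harris, dog = dog, mi = mi,
       opt = opt, sched = sched, affineOpt = affineOpt)
}

# detect + describe + match between two volumes; returns the pairs
.extractPairs <- function(fixed, moving, cfg) {
  kpF <- detectKeypoints(fixed, cfg$harris, cfg$dog)
  kpM <- detectKeypoints(moving, cfg$harris, cfg$dog)
  if (nrow(kpF) == 0 || nrow(kpM) == 0)
    return(NULL)
  fF <- computeDescriptors(fixed, kpF)
  fM <- computeDescriptors(moving, kpM)
  if (nrow(fF$vectors) == 0 || nrow(fM$vectors) == 0)
    return(NULL)
  matchFeatures(fF, fM, cfg$t4)
}

#' Build an atlas by registering images into a reference space
#'
#' Every other image is registered to the reference (affine followed by
#' MI + CP B-spline, with feature pairs auto-extracted between the
#' reference and that image) and resampled into the reference space; the
#' atlas intensity is the voxelwise mean of the reference and the
#' transformed images. Labels are carried from the reference segmentation.
#' An image whose registration fails is dropped with a warning.
#'
#' @param reference Volume defining the reference space.
#' @param referenceLabels LabelMap on the reference grid.
#' @param others list of Volumes to fold into the mean image.
#' @param cfg \code{\link{pipelineSettings}}.
#' @param phase time-phase index recorded in the atlas.
#' @return an \code{Atlas}.
#' @export
buildAtlas <- function(reference, referenceLabels, others,
                       cfg = pipelineSettings(), phase = 1L) {
  if (length(others) < 1)
    stop("at least one other image is required to build an atlas")
  acc <- reference@voxels
  used <- "reference"
  for (i in seq_along(others)) {
    res <- tryCatch({
      pairs <- .extractPairs(reference, others[[i]], cfg)
      aff <- registerAffine(reference, others[[i]], cfg$mi, cfg$affineOpt)
      tr <- registerMICP(reference, others[[i]], pairs, cfg$omega,
                         cfg$sched, cfg$mi, cfg$opt, initial = aff)
      resample(others[[i]], tr, target = reference)
    }, error = function(e) {
      warning("dropping image ", i, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      acc <- acc + res@voxels
      used <- c(used, sprintf("image%d", i))
    }
  }
  if (length(used) == 1)
    stop("atlas construction failed: every image was dropped")
  atlas(Volume(acc / length(used), reference@spacing, reference@origin),
        referenceLabels, phase = phase, provenance = used)
}

#' Propagate atlas labels through a recovered transform
#'
#' Nearest-neighbour resampling of the atlas label image through \code{T}
#' onto the target grid. \code{T} must map target-grid world coordinates
#' into atlas space, i.e. the registration was run with the unsegmented
#' image fixed and the atlas intensity moving.
#'
#' @param atl an \code{Atlas}.
#' @param transform the CompositeTransform from registration.
#' @param target grid spec (Volume or list), the unsegmented image's grid.
#' @return LabelMap on the target grid with the atlas legend.
#' @export
propagateLabels <- function(atl, transform, target) {
  resample(atl@labels, transform, target = target,
           interpolation = "nearest")
}

#' Segment an image by atlas propagation
#'
#' The full pipeline: detect keypoints in the unsegmented image and the
#' atlas intensity image (both detectors), compute and match descriptors,
#' affine pre-register, run the MI + CP B-spline registration with the
#' matched pairs (fixed = unsegmented image, moving = atlas intensity),
#' and propagate the atlas labels. If no correspondences are found the
#' registration falls back to pure MI (omega = 0) with a warning.
#'
#' @param unseg the unsegmented Volume.
#' @param atl an \code{Atlas}.
#' @param cfg \code{\link{pipelineSettings}}.
#' @return list with \code{labels} (LabelMap on the unsegmented grid),
#'   \code{transform} (CompositeTransform), \code{pairs} (data.frame used,
#'   possibly empty) and \code{metadata} (list: nPairs, omega actually
#'   used, energy trace).
#' @export
segmentImage <- function(unseg, atl, cfg = pipelineSettings()) {
  pairs <- .extractPairs(unseg, atl@intensity, cfg)
  omega <- cfg$omega
  if (is.null(pairs) || nrow(pairs) == 0) {
    warning("no feature correspondences found; falling back to pure MI")
    pairs <- NULL
    omega <- 0
  }
  aff <- registerAffine(unseg, atl@intensity, cfg$mi, cfg$affineOpt)
  tr <- registerMICP(unseg, atl@intensity, pairs, omega, cfg$sched,
                     cfg$mi, cfg$opt, initial = aff)
  labels <- propagateLabels(atl, tr, target = unseg)
  list(labels = labels, transform = tr, pairs = pairs,
       metadata = list(nPairs = if (is.null(pairs)) 0L else nrow(pairs),
                       omega = omega, trace = attr(tr, "trace")))
}
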