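#' Apply a spatial transform to world-coordinate points
#'
#' Maps points from fixed-image world coordinates (mm) to moving-image world
#' coordinates. This is the resampling convention used throughout: the
#' recovered transform carries fixed-image locations into the moving image.
#'
#' @param transform an AffineTransform, FFDTransform or CompositeTransform.
#' @param points n x 3 matrix (or length-3 vector) of world coordinates, mm.
#' @return n x 3 matrix of mapped world coordinates.
#' @export
setGeneric("transformPoints",
           function(transform, points) standardGeneric("transformPoints"))

#' Resample a Volume or LabelMap through a transform
#'
#' Each output voxel \code{v} on the target grid receives the input sampled
#' at \code{transform(world(v))}; samples falling outside the input domain
#' receive \code{default}. LabelMaps must use nearest-neighbour
#' interpolation; Volumes default to linear.
#'
#' @param vol the input Volume or LabelMap (the "moving" image).
#' @param transform maps target-grid world coordinates into \code{vol}'s
#'   world coordinates; \code{NULL} means identity.
#' @param target a Volume/LabelMap whose grid defines the output, or a list
#'   with \code{size}, \code{spacing}, \code{origin}; \code{NULL} keeps the
#'   input grid.
#' @param interpolation "linear" or "nearest".
#' @param default fill value for out-of-domain samples.
#' @return object of the same class as \code{vol} on the target grid.
#' @export
setGeneric("resample",
  function(vol, transform = NULL, target = NULL,
           interpolation = c("linear", "nearest"), default = 0)
    standardGeneric("resample"))
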