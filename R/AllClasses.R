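#' @import methods
NULL

#' Volume: a 3D scalar image on an axis-aligned grid
#'
#' The substrate of every stage of the pipeline: a dense 3D array of
#' intensities together with per-axis voxel spacing (mm) and the world
#' position (mm) of voxel (0,0,0). Geometry is axis-aligned: the world
#' coordinate of 0-based voxel index \eqn{i} is \code{origin + i * spacing};
#' no direction matrix is supported.
#'
#' @slot voxels 3D numeric array of intensities (x fastest).
#' @slot spacing numeric(3), per-axis voxel size in mm, all positive.
#' @slot origin numeric(3), world coordinate of voxel (0,0,0) in mm.
#' @export
setClass("Volume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  prototype(voxels = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("Volume", function(object) {
  if (length(dim(object@voxels)) != 3L)
    return("voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values (mm)")
  TRUE
})

#' LabelMap: an integer-valued segmentation on a Volume grid
#'
#' Shares the Volume geometry; voxel values are small non-negative integer
#' labels with a legend naming each structure. The default legend follows
#' the six-substructure cardiac convention: 0 = background, 1 = AO (aorta),
#' 2 = LA, 3 = LV, 4 = LVM, 5 = RA, 6 = RV.
#'
#' @slot legend named character vector; names are label integers as strings.
#' @export
setClass("LabelMap", contains = "Volume",
  representation(legend = "character"))

#' Default six-substructure cardiac legend
#' @export
cardiacLegend <- function() {
  c("0" = "background", "1" = "AO", "2" = "LA", "3" = "LV",
    "4" = "LVM", "5" = "RA", "6" = "RV")
}

setValidity("LabelMap", function(object) {
  v <- object@voxels
  if (any(v < 0) || any(v != round(v)))
    return("labels must be non-negative integers")
  present <- unique(as.integer(v))
  known <- as.integer(names(object@legend))
  if (length(setdiff(present, known)) > 0)
    return(sprintf("labels not in legend: %s",
                   paste(setdiff(present, known), collapse = ", ")))
  TRUE
})

#' Construct a Volume
#' @param voxels 3D numeric array.
#' @param spacing numeric(3) voxel size in mm.
#' @param origin numeric(3) world position of voxel (0,0,0) in mm.
#' @return A \code{Volume}.
#' @export
Volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("Volume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a LabelMap
#' @inheritParams Volume
#' @param legend named character vector mapping label values to names.
#' @export
LabelMap <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     legend = cardiacLegend()) {
  storage.mode(voxels) <- "integer"
  new("LabelMap", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), legend = legend)
}

#' Affine transform in world coordinates
#'
#' Maps \code{x -> matrix \%*\% (x - center) + center + translation} (mm).
#' @slot matrix 3x3 linear part.
#' @slot translation numeric(3) mm.
#' @slot center numeric(3) mm, rotation/scaling centre.
#' @export
setClass("AffineTransform",
  representation(matrix = "matrix", translation = "numeric",
                 center = "numeric"),
  prototype(matrix = diag(3), translation = c(0, 0, 0), center = c(0, 0, 0)))

setValidity("AffineTransform", function(object) {
  if (!all(dim(object@matrix) == c(3, 3)))
    return("matrix must be 3x3")
  if (abs(det(object@matrix)) < 1e-6)
    warning("affine matrix is near-singular (|det| < 1e-6)")
  TRUE
})

#' Construct an AffineTransform (identity by default)
#' @param matrix 3x3 linear part.
#' @param translation numeric(3) mm.
#' @param center numeric(3) mm.
#' @export
affineTransform <- function(matrix = diag(3), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  new("AffineTransform", matrix = matrix,
      translation = as.numeric(translation), center = as.numeric(center))
}

#' Cubic B-spline free-form deformation
#'
#' A uniform lattice of control-point displacement vectors interpolated by
#' tensor-product cubic B-splines into a dense displacement field:
#' \code{T(x) = x + sum_k w_k(x) * coefficients[k, ]}. The valid domain is
#' grid coordinate \code{t} in \code{[1, gridSize - 2]} per axis (the cubic
#' support needs one control point beyond each side); displacement is
#' continued constant outside.
#'
#' @slot gridOrigin numeric(3) mm, world position of control point (0,0,0).
#' @slot gridSpacing numeric(3) mm between control points.
#' @slot gridSize integer(3) control points per axis (each >= 4).
#' @slot coefficients K x 3 matrix of displacements (mm), x-fastest order.
#' @export
setClass("FFDTransform",
  representation(gridOrigin = "numeric", gridSpacing = "numeric",
                 gridSize = "integer", coefficients = "matrix"))

setValidity("FFDTransform", function(object) {
  if (any(object@gridSize < 4L))
    return("gridSize must be >= 4 per axis (cubic support)")
  if (any(object@gridSpacing <= 0))
    return("gridSpacing must be positive")
  K <- prod(object@gridSize)
  if (nrow(object@coefficients) != K || ncol(object@coefficients) != 3)
    return("coefficients must be prod(gridSize) x 3")
  if (any(!is.finite(object@coefficients)))
    return("coefficients must be finite")
  TRUE
})

#' Construct an FFDTransform
#' @param gridOrigin,gridSpacing,gridSize lattice geometry (mm / counts).
#' @param coefficients K x 3 displacement matrix (mm); zeros if missing.
#' @export
ffdTransform <- function(gridOrigin, gridSpacing, gridSize,
                         coefficients = NULL) {
  gridSize <- as.integer(gridSize)
  if (is.null(coefficients))
    coefficients <- matrix(0, prod(gridSize), 3)
  new("FFDTransform", gridOrigin = as.numeric(gridOrigin),
      gridSpacing = as.numeric(gridSpacing), gridSize = gridSize,
      coefficients = coefficients)
}

#' Composite transform: global affine plus local FFD displacement
#'
#' \code{T(x) = affine(x) + ffdDisplacement(x)}: the two stages are additive
#' displacement fields over the fixed-image domain, with the affine solved
#' first and frozen while the FFD is optimized.
#' @slot global an \code{AffineTransform}.
#' @slot local an \code{FFDTransform}.
#' @export
setClass("CompositeTransform",
  representation(global = "AffineTransform", local = "FFDTransform"))

#' Construct a CompositeTransform
#' @param global AffineTransform.
#' @param local FFDTransform.
#' @export
compositeTransform <- function(global, local) {
  new("CompositeTransform", global = global, local = local)
}

#' @export
setMethod("show", "Volume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("Volume %dx%dx%d, spacing %s mm, origin %s mm\n",
      d[1], d[2], d[3], paste(signif(object@spacing, 4), collapse = "x"),
      paste(signif(object@origin, 4), collapse = ",")))
  cat(sprintf("  intensity range [%g, %g]\n",
      min(object@voxels), max(object@voxels)))
})

#' @export
setMethod("show", "LabelMap", function(object) {
  d <- dim(object@voxels)
  tab <- table(object@voxels)
  cat(sprintf("LabelMap %dx%dx%d, spacing %s mm\n",
      d[1], d[2], d[3], paste(signif(object@spacing, 4), collapse = "x")))
  for (l in names(tab))
    cat(sprintf("  %s (%s): %d voxels\n", l,
        ifelse(l %in% names(object@legend), object@legend[[l]], "?"),
        as.integer(tab[[l]])))
})

#' @export
setMethod("show", "AffineTransform", function(object) {
  cat("AffineTransform\n  matrix:\n")
  print(object@matrix)
  cat(sprintf("  translation: %s mm, center: %s mm\n",
      paste(signif(object@translation, 5), collapse = ", "),
      paste(signif(object@center, 5), collapse = ", ")))
})

#' @export
setMethod("show", "FFDTransform", function(object) {
  cat(sprintf(
    "FFDTransform grid %s, spacing %s mm, max |disp| %.3g mm\n",
    paste(object@gridSize, collapse = "x"),
    paste(signif(object@gridSpacing, 4), collapse = "x"),
    max(abs(object@coefficients))))
})

#' @export
setMethod("show", "CompositeTransform", function(object) {
  cat("CompositeTransform (affine + FFD displacement)\n")
  show(object@global)
  show(object@local)
})

# ---- accessors ----

#' Grid dimensions of a Volume
#' @param x a Volume.
#' @export
setMethod("dim", "Volume", function(x) dim(x@voxels))

#' @rdname accessors
#' @param vol a Volume or LabelMap.
#' @export
voxels <- function(vol) vol@voxels

#' Accessors for grid geometry and labels
#'
#' \code{voxels}, \code{spacing}, \code{origin} return the data array and
#' grid metadata; \code{legend} the label naming of a LabelMap.
#' @name accessors
#' @rdname accessors
#' @export
spacing <- function(vol) vol@spacing

#' @rdname accessors
#' @export
origin <- function(vol) vol@origin

#' @rdname accessors
#' @export
labelLegend <- function(vol) vol@legend
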