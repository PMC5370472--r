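.gridSpec <- function(target, vol) {
  if (is.null(target)) {
    list(size = dim(vol@voxels), spacing = vol@spacing, origin = vol@origin)
  } else if (is(target, "Volume")) {
    list(size = dim(target@voxels), spacing = target@spacing,
         origin = target@origin)
  } else {
    stopifnot(all(c("size", "spacing", "origin") %in% names(target)))
    list(size = as.integer(target$size), spacing = as.numeric(target$spacing),
         origin = as.numeric(target$origin))
  }
}

# world coordinates of every voxel centre of a grid spec, x fastest
.gridWorldPoints <- function(g) {
  ix <- 0:(g$size[1] - 1); iy <- 0:(g$size[2] - 1); iz <- 0:(g$size[3] - 1)
  cbind(
    rep(g$origin[1] + ix * g$spacing[1], times = g$size[2] * g$size[3]),
    rep(rep(g$origin[2] + iy * g$spacing[2], each = g$size[1]),
        times = g$size[3]),
    rep(g$origin[3] + iz * g$spacing[3], each = g$size[1] * g$size[2]))
}

.resampleCore <- function(vol, transform, target, interpolation, default) {
  g <- .gridSpec(target, vol)
  pts <- .gridWorldPoints(g)
  if (!is.null(transform))
    pts <- transformPoints(transform, pts)
  idx <- sweep(sweep(pts, 2, vol@origin, "-"), 2, vol@spacing, "/")
  vals <- if (interpolation == "nearest")
    .nearestSample(vol@voxels, idx, default)
  else
    .trilinearSample(vol@voxels, idx, default)[, 1]
  array(vals, g$size)
}

#' @rdname resample
setMethod("resample", "Volume", function(vol, transform = NULL, target = NULL,
    interpolation = c("linear", "nearest"), default = 0) {
  interpolation <- match.arg(interpolation)
  g <- .gridSpec(target, vol)
  arr <- .resampleCore(vol, transform, target, interpolation, default)
  Volume(arr, g$spacing, g$origin)
})

#' @rdname resample
setMethod("resample", "LabelMap", function(vol, transform = NULL,
    target = NULL, interpolation = c("nearest", "linear"), default = 0) {
  interpolation <- match.arg(interpolation)
  if (interpolation != "nearest")
    stop("LabelMaps must be resampled with nearest-neighbour interpolation")
  g <- .gridSpec(target, vol)
  arr <- .resampleCore(vol, transform, target, "nearest", default)
  LabelMap(arr, g$spacing, g$origin, legend = vol@legend)
})
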