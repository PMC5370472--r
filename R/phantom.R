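# Synthetic cardiac-like data: multi-label phantom volumes, random
# ground-truth FFD warps and landmark pairs. These stand in for patient CT
# so every downstream stage can be validated against a known answer.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# structure layout in fractional world coordinates; chosen once so the six
# regions are pairwise disjoint with visible gaps
.phantomLayout <- list(
  LV  = list(label = 3L, kind = "ellipsoid", center = c(0.40, 0.55, 0.42),
             radii = c(0.13, 0.13, 0.17), intensity = 80),
  LVM = list(label = 4L, kind = "shell", center = c(0.40, 0.55, 0.42),
             radii = c(0.19, 0.19, 0.23), inner = c(0.13, 0.13, 0.17),
             intensity = 45),
  LA  = list(label = 2L, kind = "ellipsoid", center = c(0.40, 0.55, 0.76),
             radii = c(0.10, 0.10, 0.09), intensity = 75),
  RV  = list(label = 6L, kind = "ellipsoid", center = c(0.72, 0.45, 0.42),
             radii = c(0.11, 0.13, 0.15), intensity = 65),
  RA  = list(label = 5L, kind = "ellipsoid", center = c(0.72, 0.45, 0.73),
             radii = c(0.09, 0.10, 0.08), intensity = 70),
  AO  = list(label = 1L, kind = "tube", center = c(0.56, 0.30, NA),
             radius = 0.055, zrange = c(0.55, 0.92), intensity = 85))

.phantomBackground <- 5

#' Generate a six-substructure cardiac-like phantom
#'
#' Builds a deterministic multi-label volume emulating the six cardiac
#' substructures: an aortic tube (AO), the two atria (LA, RA), the two
#' ventricular blood pools (LV, RV) and a closed myocardial shell (LVM)
#' wrapped around the LV. Each structure has a distinct mean intensity on a
#' 0-100 scale; interfaces are blurred slightly so gradients are smooth,
#' and i.i.d. Gaussian noise of standard deviation \code{noiseSd} is added.
#' Labels come from the unblurred masks, assigned in a fixed priority
#' order, so they are pairwise disjoint by construction.
#'
#' @param size voxel counts per axis (each >= 32), scalar recycled.
#' @param spacing voxel size in mm.
#' @param noiseSd additive Gaussian noise standard deviation, intensity
#'   units (the intensity range is roughly 5-85).
#' @param seed integer; the output is fully determined by it
#'   (Mersenne-Twister).
#' @return list with elements \code{volume} (Volume) and \code{labels}
#'   (LabelMap with the six-substructure legend).
#' @export
makeHeartPhantom <- function(size = c(64, 64, 64), spacing = c(1, 1, 1),
                             noiseSd = 2, seed = 1) {
  size <- rep_len(as.integer(size), 3)
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(size < 32))
    stop("size must be >= 32 per axis to fit all six structures")
  extent <- (size - 1) * spacing
  # fractional coordinates of voxel centres
  u1 <- (0:(size[1] - 1)) * spacing[1] / extent[1]
  u2 <- (0:(size[2] - 1)) * spacing[2] / extent[2]
  u3 <- (0:(size[3] - 1)) * spacing[3] / extent[3]
  U1 <- array(rep(u1, times = size[2] * size[3]), size)
  U2 <- array(rep(rep(u2, each = size[1]), times = size[3]), size)
  U3 <- array(rep(u3, each = size[1] * size[2]), size)
  ell <- function(c, r)
    ((U1 - c[1]) / r[1])^2 + ((U2 - c[2]) / r[2])^2 +
      ((U3 - c[3]) / r[3])^2 <= 1
  labels <- array(0L, size)
  intens <- array(.phantomBackground, size)
  for (st in .phantomLayout) {
    mask <- switch(st$kind,
      ellipsoid = ell(st$center, st$radii),
      shell = ell(st$center, st$radii) & !ell(st$center, st$inner),
      tube = ((U1 - st$center[1])^2 + (U2 - st$center[2])^2 <=
                st$radius^2) & U3 >= st$zrange[1] & U3 <= st$zrange[2])
    mask <- mask & labels == 0L
    labels[mask] <- st$label
    intens[mask] <- st$intensity
  }
  vol <- gaussianSmooth(Volume(intens, spacing), sigma = 0.8)
  if (noiseSd > 0) {
    noise <- .withSeed(seed, rnorm(length(intens), 0, noiseSd))
    vol@voxels <- vol@voxels + array(noise, size)
  }
  list(volume = vol, labels = LabelMap(labels, spacing))
}

#' Random ground-truth B-spline warp
#'
#' Control-point displacements are i.i.d. uniform in
#' \code{[-maxDisp, maxDisp]} per axis; the outermost ring of lattice
#' points is frozen at zero so the warp stays near identity at the volume
#' edges. By the B-spline partition of unity the displacement magnitude
#' never exceeds \code{maxDisp} per axis.
#'
#' @param domain a Volume whose world extent the lattice must cover.
#' @param gridSpacing control-point spacing in mm (the warp's smoothness
#'   scale).
#' @param maxDisp maximum per-axis control-point displacement, mm.
#' @param seed integer seed; fully deterministic.
#' @return an FFDTransform.
#' @export
makeRandomFFD <- function(domain, gridSpacing, maxDisp, seed = 1) {
  if (maxDisp < 0) stop("maxDisp must be >= 0")
  ffd <- ffdGrid(domain, gridSpacing)
  K <- ffd@gridSize
  co <- matrix(.withSeed(seed, runif(prod(K) * 3, -maxDisp, maxDisp)),
               prod(K), 3)
  ix <- arrayInd(seq_len(prod(K)), K)
  boundary <- ix[, 1] %in% c(1L, K[1]) | ix[, 2] %in% c(1L, K[2]) |
              ix[, 3] %in% c(1L, K[3])
  co[boundary, ] <- 0
  ffd@coefficients <- co
  ffd
}

# face-neighbour boundary voxels of a label array (any label > 0 against a
# different value); returns a logical array
.surfaceMask <- function(lab, value = NULL) {
  m <- if (is.null(value)) lab > 0L else lab == value
  d <- dim(m)
  shift <- function(a, ax, by) {
    out <- a
    idx <- lapply(d, seq_len)
    src <- idx; dst <- idx
    n <- d[ax]
    if (by > 0) { dst[[ax]] <- (1 + by):n; src[[ax]] <- 1:(n - by) }
    else { dst[[ax]] <- 1:(n + by); src[[ax]] <- (1 - by):n }
    out[] <- FALSE
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  border <- array(FALSE, d)
  for (ax in 1:3) for (by in c(-1, 1))
    border <- border | (m & !shift(m, ax, by))
  border
}

#' Build a complete synthetic registration case
#'
#' Generates a noise-free phantom, applies a random ground-truth FFD warp
#' \code{T} (fixed-to-moving convention), and returns the warped image as
#' the fixed image and the original phantom as the moving image, each with
#' independent additive noise, so that \code{resample(moving, T)} aligns
#' with \code{fixed} exactly before noise. Landmarks are sampled on
#' structure boundaries of the fixed image (mirroring where feature
#' detectors fire on real anatomy) with
#' \code{xM = T(xF) + N(0, landmarkNoise)}.
#'
#' @param size,spacing phantom grid (see \code{\link{makeHeartPhantom}}).
#' @param warpSpacing control-point spacing of the ground-truth warp, mm.
#' @param maxDisp maximum control-point displacement, mm.
#' @param noiseSd additive intensity noise (both images, independent).
#' @param nLandmarks number of landmark pairs.
#' @param landmarkNoise isotropic Gaussian jitter applied to the moving
#'   landmark, mm.
#' @param seed integer master seed.
#' @return list with \code{fixed}, \code{moving} (Volumes),
#'   \code{fixedLabels}, \code{movingLabels} (LabelMaps),
#'   \code{trueTransform} (FFDTransform, fixed-to-moving), \code{pairs}
#'   (data.frame xF, yF, zF, xM, yM, zM), and \code{seed}.
#' @export
makeRegistrationCase <- function(size = c(64, 64, 64), spacing = c(1, 1, 1),
                                 warpSpacing = 16, maxDisp = 6, noiseSd = 2,
                                 nLandmarks = 40, landmarkNoise = 0.5,
                                 seed = 1) {
  base <- makeHeartPhantom(size, spacing, noiseSd = 0, seed = seed)
  trueT <- makeRandomFFD(base$volume, warpSpacing, maxDisp, seed = seed + 101)
  fixedClean <- resample(base$volume, trueT)
  fixedLabels <- resample(base$labels, trueT)
  moving <- base$volume
  movingLabels <- base$labels
  if (noiseSd > 0) {
    n <- prod(dim(fixedClean))
    nz <- .withSeed(seed + 202, rnorm(2 * n, 0, noiseSd))
    fixedClean@voxels <- fixedClean@voxels + array(nz[1:n], dim(fixedClean))
    moving@voxels <- moving@voxels + array(nz[(n + 1):(2 * n)], dim(moving))
  }
  # landmarks on fixed-image structure boundaries, away from the border
  surf <- .surfaceMask(fixedLabels@voxels)
  d <- dim(surf)
  margin <- 6L
  ix <- which(surf, arr.ind = TRUE)
  keep <- ix[, 1] > margin & ix[, 1] <= d[1] - margin &
          ix[, 2] > margin & ix[, 2] <= d[2] - margin &
          ix[, 3] > margin & ix[, 3] <= d[3] - margin
  ix <- ix[keep, , drop = FALSE]
  if (nrow(ix) < nLandmarks)
    stop("not enough boundary voxels for the requested landmarks")
  sel <- .withSeed(seed + 303, sample.int(nrow(ix), nLandmarks))
  xF <- indexToWorld(fixedClean, ix[sel, , drop = FALSE] - 1)
  xM <- transformPoints(trueT, xF)
  if (landmarkNoise > 0)
    xM <- xM + matrix(.withSeed(seed + 404,
                                rnorm(3 * nLandmarks, 0, landmarkNoise)),
                      nLandmarks, 3)
  pairs <- data.frame(xF = xF[, 1], yF = xF[, 2], zF = xF[, 3],
                      xM = xM[, 1], yM = xM[, 2], zM = xM[, 3])
  list(fixed = fixedClean, moving = moving, fixedLabels = fixedLabels,
       movingLabels = movingLabels, trueTransform = trueT, pairs = pairs,
       seed = seed)
}
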