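# Distinctive-point detection: scale-adapted multi-scale Harris corners and
# local extrema in a difference-of-Gaussians scale space. Intensities are
# min-max normalized to [0, 1] before detection so the absolute response
# thresholds are meaningful across inputs.

#' Parameters of the multi-scale Harris detector
#'
#' @param sigmaIList integration scales in voxels, strictly increasing
#'   (default \code{1.5 * 2^(0:4)}).
#' @param sigmaDRatio differentiation scale as a fraction of the
#'   integration scale (default 0.7).
#' @param alpha trace weight in the corner response
#'   \code{det(H) - alpha * trace(H)^3}. By the AM-GM inequality
#'   \code{det(H) <= trace(H)^3 / 27} for the positive-semidefinite
#'   autocorrelation matrix, so the response can only be positive for
#'   \code{alpha < 1/27}; the default 0.006 reproduces the corner margin
#'   of the classic 2D detector (0.04 with the squared trace).
#' @param t1 corner-response candidate threshold (default 0.1).
#' @param t2 Laplacian-of-Gaussian scale-selection threshold (default 0.1).
#' @param logIncludeZz include the \code{L_zz} term in the LoG scale
#'   selection operator. The default (FALSE) uses the two-term
#'   \code{sigma^2 |L_xx + L_yy|} form; the three-term form treats the
#'   axes symmetrically.
#' @return a list of validated parameters.
#' @export
harrisParams <- function(sigmaIList = 1.5 * 2^(0:4), sigmaDRatio = 0.7,
                         alpha = 0.006, t1 = 0.1, t2 = 0.1,
                         logIncludeZz = FALSE) {
  stopifnot(all(sigmaIList > 0), all(diff(sigmaIList) > 0),
            sigmaDRatio > 0, alpha > 0, t1 > 0, t2 > 0)
  list(sigmaIList = sigmaIList, sigmaDRatio = sigmaDRatio, alpha = alpha,
       t1 = t1, t2 = t2, logIncludeZz = logIncludeZz)
}

#' Parameters of the DoG extrema detector
#'
#' @param levels pyramid levels (octaves), each downsampled from the last.
#' @param blurSigma base Gaussian scale in voxels (default 1.5).
#' @param scaleFactor integer per-level downsampling factor (default 2).
#' @param scalesPerLevel DoG images per level (default 5; must be >= 3 so
#'   interior scales have both neighbours). Only the
#'   \code{scalesPerLevel - 2} interior DoG images can host extrema, so
#'   the blur ladder uses the ratio \code{2^(1/(scalesPerLevel - 2))},
#'   which makes the interior bands of one level tile exactly one octave
#'   and join contiguously with the next (decimated) level.
#' @param t3 extremum magnitude threshold on normalized intensities
#'   (default 0.0075).
#' @export
dogParams <- function(levels = 3, blurSigma = 1.5, scaleFactor = 2,
                      scalesPerLevel = 5, t3 = 0.0075) {
  stopifnot(levels >= 1, blurSigma > 0, scaleFactor > 1,
            scaleFactor == round(scaleFactor), scalesPerLevel >= 3, t3 >= 0)
  list(levels = as.integer(levels), blurSigma = blurSigma,
       scaleFactor = as.integer(scaleFactor),
       scalesPerLevel = as.integer(scalesPerLevel), t3 = t3)
}

#' Scale-adapted Harris corner response
#'
#' The second-moment matrix at each voxel is
#' \code{H = sigmaD^2 * g(sigmaI) \* [outer products of Gaussian
#' derivatives at sigmaD]}, and the response is
#' \code{det(H) - alpha * trace(H)^3}. Scales are in voxel units of the
#' finest axis; with anisotropic spacing the per-axis sigma is rescaled so
#' smoothing is physically isotropic in mm. The input is used as given (no
#' normalization); normalize first if thresholding against \code{t1}.
#'
#' @param vol a Volume.
#' @param sigmaI integration (smoothing) scale, voxels.
#' @param sigmaD differentiation scale, voxels.
#' @param alpha trace weight.
#' @return a Volume of responses on the same grid.
#' @export
harrisResponse <- function(vol, sigmaI, sigmaD, alpha = 0.04) {
  if (sigmaI <= 0 || sigmaD <= 0) stop("sigmaI and sigmaD must be positive")
  sI <- .isoSigmaVoxels(sigmaI, vol@spacing)
  sD <- .isoSigmaVoxels(sigmaD, vol@spacing)
  arr <- vol@voxels
  Lx <- .gaussDeriv(arr, sD, 1)
  Ly <- .gaussDeriv(arr, sD, 2)
  Lz <- .gaussDeriv(arr, sD, 3)
  sm <- function(a) {
    for (ax in 1:3) a <- .conv1dReflect(a, .gaussKernel(sI[ax]),
                                        as.integer(ax - 1))
    a
  }
  s2 <- sigmaD^2
  Wxx <- s2 * sm(Lx * Lx); Wyy <- s2 * sm(Ly * Ly); Wzz <- s2 * sm(Lz * Lz)
  Wxy <- s2 * sm(Lx * Ly); Wxz <- s2 * sm(Lx * Lz); Wyz <- s2 * sm(Ly * Lz)
  detH <- Wxx * (Wyy * Wzz - Wyz^2) - Wxy * (Wxy * Wzz - Wyz * Wxz) +
          Wxz * (Wxy * Wyz - Wyy * Wxz)
  trH <- Wxx + Wyy + Wzz
  Volume(detH - alpha * trH^3, vol@spacing, vol@origin)
}

# LoG scale-selection operator sigma^2 |L_xx + L_yy (+ L_zz)|
.logOperator <- function(arr, spacing, sigma, includeZz) {
  s <- .isoSigmaVoxels(sigma, spacing)
  lap <- .gaussDeriv2(arr, s, 1) + .gaussDeriv2(arr, s, 2)
  if (includeZz) lap <- lap + .gaussDeriv2(arr, s, 3)
  sigma^2 * abs(lap)
}

#' Multi-scale Harris keypoint detection
#'
#' A voxel becomes a keypoint with characteristic scale \code{sigma_i} iff
#' (a) its corner response at \code{sigma_i} exceeds \code{t1}, (b) it is a
#' strict spatial maximum of that response over its 26-neighbourhood, and
#' (c) the LoG operator at \code{sigma_i} exceeds both neighbouring scales
#' and \code{t2}. Endpoint scales cannot be selected. The volume is min-max
#' normalized to [0, 1] internally.
#'
#' @param vol a Volume.
#' @param params a \code{\link{harrisParams}} list.
#' @return data.frame of keypoints: world position (x, y, z, mm), 0-based
#'   voxel index (ix, iy, iz), scale (voxels), response, detector tag.
#' @export
detectHarris <- function(vol, params = harrisParams()) {
  sig <- params$sigmaIList
  if (length(sig) < 3)
    stop("at least 3 integration scales are required for scale selection")
  nvol <- Volume(.normalize01(vol@voxels), vol@spacing, vol@origin)
  logs <- lapply(sig, function(s)
    .logOperator(nvol@voxels, vol@spacing, s, params$logIncludeZz))
  kp <- list()
  for (i in seq_along(sig)[-c(1, length(sig))]) {
    resp <- harrisResponse(nvol, sig[i], params$sigmaDRatio * sig[i],
                           params$alpha)
    # the candidate threshold is a fraction of the peak response: the
    # corner response scales with the 6th power of the intensity range,
    # so an absolute cut is meaningless on normalized volumes
    rmax <- max(resp@voxels)
    if (rmax <= 0) next
    cand <- .localMaxima26(resp@voxels, params$t1 * rmax)
    if (nrow(cand) == 0) next
    lin <- 1 + cand[, 1] + cand[, 2] * dim(vol)[1] +
           cand[, 3] * dim(vol)[1] * dim(vol)[2]
    li <- logs[[i]][lin]
    ok <- li > logs[[i - 1]][lin] & li > logs[[i + 1]][lin] & li > params$t2
    if (!any(ok)) next
    sel <- cand[ok, , drop = FALSE]
    kp[[length(kp) + 1]] <- data.frame(
      ix = sel[, 1], iy = sel[, 2], iz = sel[, 3],
      scale = sig[i], response = sel[, 4])
  }
  .finishKeypoints(kp, vol, "harris")
}

.finishKeypoints <- function(kp, vol, tag) {
  if (length(kp) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      ix = numeric(0), iy = numeric(0), iz = numeric(0),
                      scale = numeric(0), response = numeric(0),
                      detector = character(0)))
  df <- do.call(rbind, kp)
  w <- indexToWorld(vol, as.matrix(df[, c("ix", "iy", "iz")]))
  data.frame(x = w[, 1], y = w[, 2], z = w[, 3],
             ix = df$ix, iy = df$iy, iz = df$iz,
             scale = df$scale, response = df$response,
             detector = tag)
}

#' Build a difference-of-Gaussians pyramid
#'
#' Level 1 is the min-max-normalized input; each further level smooths by
#' \code{blurSigma} and decimates by \code{scaleFactor}. Within a level,
#' \code{scalesPerLevel + 1} progressively blurred images (scales
#' \code{blurSigma * k^j} with \code{k = 2^(1/(scalesPerLevel - 2))})
#' yield \code{scalesPerLevel} DoG images by adjacent differences; the
#' interior DoG bands then span one full octave per level.
#'
#' @param vol a Volume.
#' @param params a \code{\link{dogParams}} list.
#' @return list of levels, each with \code{base} (Volume), \code{dog}
#'   (list of Volumes), \code{sigmas} (effective scale of each DoG image in
#'   level-0 voxels) and \code{factor} (cumulative decimation).
#' @export
buildDoGPyramid <- function(vol, params = dogParams()) {
  f <- params$scaleFactor
  minSize <- min(dim(vol)) %/% f^(params$levels - 1)
  if (minSize < 8)
    stop("input too small for ", params$levels, " pyramid levels ",
         "(coarsest level must be >= 8 voxels per axis)")
  base <- Volume(.normalize01(vol@voxels), vol@spacing, vol@origin)
  s <- params$scalesPerLevel
  k <- 2^(1 / max(s - 2, 1))
  levels <- vector("list", params$levels)
  cumFactor <- 1L
  for (lv in seq_len(params$levels)) {
    sigmas <- params$blurSigma * k^(0:s)
    blurred <- lapply(sigmas, function(sg) gaussianSmooth(base, sg))
    dog <- lapply(seq_len(s), function(j)
      Volume(blurred[[j + 1]]@voxels - blurred[[j]]@voxels,
             base@spacing, base@origin))
    levels[[lv]] <- list(base = base, dog = dog,
                         # effective scale of a DoG band: geometric mean
                         # of its two blur scales, in level-0 voxels
                         sigmas = sqrt(sigmas[1:s] * sigmas[2:(s + 1)]) *
                                  cumFactor,
                         factor = cumFactor)
    if (lv < params$levels) {
      sm <- gaussianSmooth(base, params$blurSigma)
      d <- dim(sm)
      idx <- lapply(d, function(n) seq(1, n, by = f))
      base <- Volume(sm@voxels[idx[[1]], idx[[2]], idx[[3]]],
                     base@spacing * f, base@origin)
      cumFactor <- cumFactor * f
    }
  }
  structure(list(levels = levels, params = params), class = "dogPyramid")
}

#' Detect extrema in a DoG pyramid
#'
#' A voxel of an interior DoG image is a keypoint iff its magnitude exceeds
#' \code{t3} and it is a strict maximum or strict minimum over its 26
#' spatial neighbours plus the full 27-voxel blocks at the scales above and
#' below (80 comparisons). Positions are reported in level-0 world
#' coordinates; ties (plateaus) are never extrema.
#'
#' @param pyramid result of \code{\link{buildDoGPyramid}}.
#' @param t3 magnitude threshold (default from the pyramid's params).
#' @return keypoint data.frame as in \code{\link{detectHarris}}, with
#'   detector tag "dog".
#' @export
detectDoGExtrema <- function(pyramid, t3 = pyramid$params$t3) {
  kp <- list()
  vol0 <- pyramid$levels[[1]]$base
  for (lv in pyramid$levels) {
    nd <- length(lv$dog)
    if (nd < 3)
      stop("each pyramid level needs >= 3 DoG images for extrema detection")
    for (j in 2:(nd - 1)) {
      hits <- .dogExtrema(lv$dog[[j - 1]]@voxels, lv$dog[[j]]@voxels,
                          lv$dog[[j + 1]]@voxels, t3)
      if (nrow(hits) == 0) next
      # map level indices to level-0 continuous indices
      kp[[length(kp) + 1]] <- data.frame(
        ix = hits[, 1] * lv$factor, iy = hits[, 2] * lv$factor,
        iz = hits[, 3] * lv$factor,
        scale = lv$sigmas[j], response = hits[, 4])
    }
  }
  .finishKeypoints(kp, vol0, "dog")
}

#' Detect keypoints with both detectors
#'
#' Concatenates multi-scale Harris corners and DoG extrema (both detector
#' families contribute matched points in the registration pipeline).
#'
#' @param vol a Volume.
#' @param harris a \code{\link{harrisParams}} list, or NULL to skip.
#' @param dog a \code{\link{dogParams}} list, or NULL to skip.
#' @return combined keypoint data.frame.
#' @export
detectKeypoints <- function(vol, harris = harrisParams(),
                            dog = dogParams()) {
  out <- list()
  if (!is.null(harris)) out$h <- detectHarris(vol, harris)
  if (!is.null(dog)) out$d <- detectDoGExtrema(buildDoGPyramid(vol, dog))
  do.call(rbind, unname(out))
}
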