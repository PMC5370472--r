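# Registration drivers: mutual-information affine pre-alignment and the
# coarse-to-fine MI + corresponding-point B-spline registration. The
# recovered transform maps fixed-image world coordinates into the moving
# image (resampling convention): resample(moving, T, fixed) aligns the
# moving image onto the fixed grid.

#' Multiresolution schedule for the B-spline registration
#'
#' Consecutive grid spacings must halve (the level transfer uses exact
#' dyadic B-spline subdivision). Smoothing is applied to the moving image
#' only, as a Gaussian in voxel units — coarse levels are smoothed, not
#' downsampled.
#'
#' @param smoothingSigmas per-level Gaussian sigma in voxels
#'   (default 8, 4, 2, 1).
#' @param gridSpacings per-level control-point spacing in mm
#'   (default 80, 40, 20, 10).
#' @export
multiresSchedule <- function(smoothingSigmas = c(8, 4, 2, 1),
                             gridSpacings = c(80, 40, 20, 10)) {
  stopifnot(length(smoothingSigmas) == length(gridSpacings),
            all(diff(smoothingSigmas) < 0) || length(smoothingSigmas) == 1,
            all(gridSpacings > 0))
  if (length(gridSpacings) > 1 &&
      any(abs(gridSpacings[-length(gridSpacings)] / gridSpacings[-1] - 2)
          > 1e-9))
    stop("consecutive grid spacings must halve (dyadic refinement)")
  list(smoothingSigmas = smoothingSigmas, gridSpacings = gridSpacings)
}

#' Affine pre-registration by mutual information
#'
#' Optimizes the 12 affine parameters (matrix + translation about the
#' fixed-image centre) to minimize -MI with stochastic gradient descent,
#' over a two-level smoothing schedule applied to the moving image.
#' Matrix parameters are rescaled by the domain radius so matrix and
#' translation steps are commensurate. Returns the identity (with a
#' warning) if the solution degenerates to a near-singular matrix.
#'
#' @param fixed,moving Volumes with overlapping fields of view.
#' @param settings \code{\link{miSettings}}.
#' @param opt \code{\link{asgdSettings}}.
#' @param smoothingSigmas per-level moving-image smoothing, voxels.
#' @return an AffineTransform mapping fixed world coordinates into the
#'   moving image.
#' @export
registerAffine <- function(fixed, moving, settings = miSettings(),
                           opt = asgdSettings(),
                           smoothingSigmas = c(4, 2)) {
  set.seed(opt$seed)
  halfExtent <- (dim(fixed) - 1) * fixed@spacing / 2
  center <- fixed@origin + halfExtent
  radius <- sqrt(mean(halfExtent^2))
  mu <- c(as.vector(diag(3)), c(0, 0, 0))
  scales <- c(rep(radius, 9), rep(1, 3))
  for (sg in smoothingSigmas) {
    movS <- if (sg > 0) gaussianSmooth(moving, sg) else moving
    cost <- function(mu, k) {
      aff <- affineTransform(matrix(mu[1:9], 3, 3), mu[10:12], center)
      pts <- .drawSamples(fixed, settings)
      mapped <- transformPoints(aff, pts)
      pe <- .parzenMIAlpha(fixed, movS, pts, mapped, settings$bins)
      xc <- sweep(pe$ptsIn, 2, center, "-")
      gmat <- t(pe$alpha) %*% xc              # [component, coordinate]
      list(E = -pe$mi, gradient = c(as.vector(gmat), colSums(pe$alpha)))
    }
    res <- asgdMinimize(cost, mu, opt, scales, tailAverage = 0.25)
    mu <- res$mu
  }
  m <- matrix(mu[1:9], 3, 3)
  if (abs(det(m)) < 1e-6) {
    warning("affine registration degenerated to a singular matrix; ",
            "falling back to the identity")
    return(affineTransform(center = center))
  }
  affineTransform(m, mu[10:12], center)
}

#' Coarse-to-fine MI + corresponding-point B-spline registration
#'
#' At each level the moving image is Gaussian-smoothed with the level's
#' sigma, the control lattice is refined to the level's spacing (exact
#' dyadic B-spline subdivision carries the coarse solution over), and the
#' energy \code{E = -MI + omega * C_p} is minimized over the FFD
#' coefficients by stochastic gradient descent, re-drawing the MI samples
#' every iteration. The affine stage is frozen throughout. With
#' \code{omega = 0} (or no pairs) this degenerates to pure MI FFD
#' registration.
#'
#' @param fixed,moving Volumes.
#' @param pairs correspondence data.frame in fixed-image world
#'   coordinates, or NULL.
#' @param omega penalty weight (default 0.01, with C_p in mm).
#' @param sched \code{\link{multiresSchedule}}.
#' @param settings \code{\link{miSettings}}.
#' @param opt \code{\link{asgdSettings}} (iterations are per level).
#' @param initial affine pre-alignment (e.g. from
#'   \code{\link{registerAffine}}); identity if NULL.
#' @return a CompositeTransform; attribute \code{"trace"} holds the
#'   per-level energy traces.
#' @export
registerMICP <- function(fixed, moving, pairs = NULL, omega = 0.01,
                         sched = multiresSchedule(),
                         settings = miSettings(), opt = asgdSettings(),
                         initial = NULL) {
  stopifnot(omega >= 0)
  if (is.null(initial)) {
    halfExtent <- (dim(fixed) - 1) * fixed@spacing / 2
    initial <- affineTransform(center = fixed@origin + halfExtent)
  }
  set.seed(opt$seed)
  usePairs <- !is.null(pairs) && nrow(pairs) > 0 && omega > 0
  if (usePairs) {
    # drop pairs whose initial mapping already leaves the moving domain
    mapped <- transformPoints(initial, as.matrix(pairs[, c("xF", "yF", "zF")]))
    idx <- sweep(sweep(mapped, 2, moving@origin, "-"), 2, moving@spacing, "/")
    d <- dim(moving)
    inside <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
              idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
              idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
    if (!all(inside)) {
      warning(sum(!inside), " pair(s) map outside the moving domain and ",
              "were down-weighted to zero")
      pairs <- pairs[inside, , drop = FALSE]
      usePairs <- nrow(pairs) > 0
    }
  }
  nLevels <- length(sched$gridSpacings)
  ffd <- ffdGrid(fixed, sched$gridSpacings[1])
  traces <- vector("list", nLevels)
  for (L in seq_len(nLevels)) {
    if (L > 1) ffd <- refineFFD(ffd)
    sg <- sched$smoothingSigmas[L]
    movS <- if (sg > 0) gaussianSmooth(moving, sg) else moving
    K <- nrow(ffd@coefficients)
    gridCache <- ffd
    cost <- function(mu, k) {
      f2 <- gridCache
      f2@coefficients <- matrix(mu, K, 3)
      res <- energyAndGradient(fixed, movS,
                               if (usePairs) pairs else NULL,
                               compositeTransform(initial, f2),
                               omega = if (usePairs) omega else 0,
                               settings = settings)
      list(E = res$E, gradient = as.vector(res$gradient))
    }
    res <- asgdMinimize(cost, as.vector(ffd@coefficients), opt)
    ffd@coefficients <- matrix(res$mu, K, 3)
    traces[[L]] <- res$trace
  }
  out <- compositeTransform(initial, ffd)
  attr(out, "trace") <- traces
  out
}
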