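# Registration similarity and penalty: mutual information estimated from a
# joint intensity histogram, the corresponding-point (CP) mean-distance
# penalty, and the combined registration energy E = -MI + omega * C_p with
# its analytic gradient with respect to the B-spline coefficients.

#' Mutual-information estimation settings
#'
#' @param bins joint-histogram bins per axis (default 32).
#' @param nSamples spatial samples per evaluation (default 2048; must be at
#'   least \code{bins^2}).
#' @param sampler "random" draws uniform points in the fixed-image domain
#'   from the current RNG stream (re-drawn each evaluation, as the
#'   stochastic optimizer expects); "grid" uses a deterministic strided
#'   subset of voxel centres.
#' @param seed seed applied by the top-level registration drivers before
#'   their optimization loops (individual metric evaluations draw from the
#'   current RNG stream).
#' @export
miSettings <- function(bins = 32, nSamples = 2048,
                       sampler = c("random", "grid"), seed = 1) {
  sampler <- match.arg(sampler)
  stopifnot(bins >= 2, nSamples >= bins^2)
  list(bins = as.integer(bins), nSamples = as.integer(nSamples),
       sampler = sampler, seed = seed)
}

# sample points in fixed-image world coordinates
.drawSamples <- function(fixed, settings) {
  d <- dim(fixed)
  if (settings$sampler == "grid") {
    nvox <- prod(d)
    pts <- .gridWorldPoints(list(size = d, spacing = fixed@spacing,
                                 origin = fixed@origin))
    if (nvox > settings$nSamples) {
      stride <- ceiling(nvox / settings$nSamples)
      pts <- pts[seq(1, nvox, by = stride), , drop = FALSE]
    }
    pts
  } else {
    lo <- fixed@origin
    hi <- fixed@origin + (d - 1) * fixed@spacing
    n <- settings$nSamples
    cbind(stats::runif(n, lo[1], hi[1]), stats::runif(n, lo[2], hi[2]),
          stats::runif(n, lo[3], hi[3]))
  }
}

.hardBin <- function(v, rng, bins) {
  if (rng[2] <= rng[1]) return(rep(0L, length(v)))
  b <- floor((v - rng[1]) / (rng[2] - rng[1]) * bins)
  as.integer(pmax(0, pmin(bins - 1, b)))
}

#' Mutual information between a fixed and a transformed moving image
#'
#' \code{MI = sum_f sum_m p(f,m) log2( p(f,m) / (pF(f) pM(m)) )}, with the
#' joint probability estimated from the hard-binned histogram of
#' (fixed intensity, moving intensity at \code{T(x)}) over the sampled
#' points; moving intensities are linearly interpolated and the marginals
#' are obtained by summing the joint histogram. Samples mapping outside the
#' moving domain are dropped (a warning is raised if more than half are).
#'
#' @param fixed,moving Volumes.
#' @param transform maps fixed world coordinates into the moving image;
#'   NULL for identity.
#' @param settings \code{\link{miSettings}}; use \code{sampler = "grid"}
#'   with \code{nSamples >= prod(dim(fixed))} for full-grid (deterministic)
#'   estimation.
#' @return MI in bits (scalar).
#' @export
mutualInformation <- function(fixed, moving, transform = NULL,
                              settings = miSettings()) {
  pts <- .drawSamples(fixed, settings)
  fIdx <- sweep(sweep(pts, 2, fixed@origin, "-"), 2, fixed@spacing, "/")
  fs <- .trilinearSample(fixed@voxels, fIdx, NA_real_)
  mapped <- if (is.null(transform)) pts else transformPoints(transform, pts)
  mIdx <- sweep(sweep(mapped, 2, moving@origin, "-"), 2, moving@spacing, "/")
  ms <- .trilinearSample(moving@voxels, mIdx, NA_real_)
  inside <- fs[, 5] > 0 & ms[, 5] > 0
  if (!any(inside))
    stop("no samples map inside the moving image domain")
  if (mean(inside) < 0.5)
    warning("fewer than 50% of samples map inside the moving image domain")
  f <- fs[inside, 1]; m <- ms[inside, 1]
  bins <- settings$bins
  fb <- .hardBin(f, range(fixed@voxels), bins)
  mb <- .hardBin(m, range(moving@voxels), bins)
  counts <- tabulate(fb * bins + mb + 1L, nbins = bins * bins)
  p <- counts / sum(counts)
  jp <- matrix(p, bins, bins, byrow = TRUE)  # [fixed, moving]
  pF <- rowSums(jp); pM <- colSums(jp)
  nz <- jp > 0
  sum(jp[nz] * log2(jp[nz] / outer(pF, pM)[nz]))
}

#' Corresponding-point penalty
#'
#' The mean Euclidean distance (mm) between the moving-image landmarks and
#' the transformed fixed-image landmarks:
#' \code{C_p = (1/P) sum_i || xM_i - T(xF_i) ||}.
#'
#' @param pairs data.frame with columns xF, yF, zF, xM, yM, zM (mm).
#' @param transform applied to the fixed points; NULL for identity.
#' @return mean distance in mm.
#' @export
cpPenalty <- function(pairs, transform = NULL) {
  if (is.null(pairs) || nrow(pairs) < 1)
    stop("at least one corresponding pair is required")
  xF <- as.matrix(pairs[, c("xF", "yF", "zF")])
  xM <- as.matrix(pairs[, c("xM", "yM", "zM")])
  mapped <- if (is.null(transform)) xF else transformPoints(transform, xF)
  mean(sqrt(rowSums((xM - mapped)^2)))
}

# continuous moving-bin coordinate: intensity range mapped onto [1, B-2]
# so the cubic Parzen support always stays inside the histogram
.parzenCoord <- function(v, rng, bins) {
  w <- (rng[2] - rng[1]) / (bins - 3)
  if (w <= 0) return(list(coord = rep(1, length(v)), width = 1))
  list(coord = 1 + (v - rng[1]) / w, width = w)
}

#' Registration energy and its gradient in the FFD coefficients
#'
#' Computes \code{E = -MI + omega * C_p} and its analytic gradient with
#' respect to the B-spline control-point displacements. The energy is
#' minimized, so a better MI lowers E. For the gradient the joint
#' histogram uses a cubic B-spline Parzen window on the moving-intensity
#' axis (hard binning on the fixed axis), which makes MI differentiable in
#' the transform parameters; the MI term of the gradient is
#' \code{dMI/dmu = sum_i dMI/dm_i * grad(M)(T(x_i)) * dT/dmu(x_i)} and the
#' penalty term is \code{-(omega/P) sum_i unit(xM_i - T(xF_i)) *
#' dT/dmu(xF_i)}, with pairs closer than 1e-9 mm contributing zero
#' (subgradient at the kink). Affine parameters are held fixed.
#'
#' @param fixed,moving Volumes.
#' @param pairs correspondence data.frame, or NULL for \code{omega = 0}.
#' @param transform a CompositeTransform (or bare FFDTransform) whose FFD
#'   coefficients are the free parameters.
#' @param omega penalty weight (C_p in mm; default 0.01).
#' @param settings \code{\link{miSettings}}.
#' @param samplePoints optional n x 3 matrix of fixed-image world sample
#'   points; when NULL they are drawn per \code{settings}.
#' @param miGradient "analytic" (default) or "fd" (central finite
#'   differences over every coefficient; slow, validation only).
#' @return list with \code{E}, \code{gradient} (K x 3 matrix matching the
#'   FFD coefficients), \code{mi}, \code{cp}, \code{samplePoints}.
#' @export
energyAndGradient <- function(fixed, moving, pairs, transform,
                              omega = 0.01, settings = miSettings(),
                              samplePoints = NULL,
                              miGradient = c("analytic", "fd")) {
  miGradient <- match.arg(miGradient)
  stopifnot(omega >= 0)
  if (is(transform, "CompositeTransform")) {
    affine <- transform@global; ffd <- transform@local
  } else if (is(transform, "FFDTransform")) {
    affine <- affineTransform(); ffd <- transform
  } else stop("transform must be a CompositeTransform or FFDTransform")
  if (is.null(samplePoints)) samplePoints <- .drawSamples(fixed, settings)
  if (miGradient == "fd")
    return(.energyGradientFD(fixed, moving, pairs, affine, ffd, omega,
                             settings, samplePoints))
  ev <- .parzenEnergy(fixed, moving, affine, ffd, samplePoints, settings)
  E <- -ev$mi
  grad <- ev$miGrad          # gradient of -MI already
  cp <- 0
  if (!is.null(pairs) && nrow(pairs) > 0 && omega > 0) {
    xF <- as.matrix(pairs[, c("xF", "yF", "zF")])
    xM <- as.matrix(pairs[, c("xM", "yM", "zM")])
    mapped <- transformPoints(affine, xF) + ffdDisplacement(ffd, xF)
    r <- xM - mapped
    nrm <- sqrt(rowSums(r^2))
    cp <- mean(nrm)
    P <- nrow(pairs)
    unit <- r / ifelse(nrm > 1e-9, nrm, Inf)   # zero rows at the kink
    grad <- grad + .ffdScatter(ffd@gridOrigin, ffd@gridSpacing,
                               ffd@gridSize, xF, -(omega / P) * unit)
    E <- E + omega * cp
  } else if (!is.null(pairs) && nrow(pairs) > 0) {
    cp <- cpPenalty(pairs, compositeTransform(affine, ffd))
  }
  list(E = E, gradient = grad, mi = ev$mi, cp = cp,
       samplePoints = samplePoints)
}

# Parzen-window MI between fixed samples and the moving image at mapped
# points: returns the MI value and, per inside sample, the gradient of
# -MI with respect to the mapped world position (alpha, n x 3 mm^-1).
.parzenMIAlpha <- function(fixed, moving, pts, mapped, bins,
                           valueOnly = FALSE) {
  fIdx <- sweep(sweep(pts, 2, fixed@origin, "-"), 2, fixed@spacing, "/")
  fs <- .trilinearSample(fixed@voxels, fIdx, NA_real_)
  mIdx <- sweep(sweep(mapped, 2, moving@origin, "-"), 2, moving@spacing, "/")
  ms <- .trilinearSample(moving@voxels, mIdx, NA_real_)
  inside <- fs[, 5] > 0 & ms[, 5] > 0
  if (!any(inside)) stop("no samples map inside the moving image domain")
  if (mean(inside) < 0.5)
    warning("fewer than 50% of samples map inside the moving image domain")
  ptsIn <- pts[inside, , drop = FALSE]
  fb <- .hardBin(fs[inside, 1], range(fixed@voxels), bins)
  pz <- .parzenCoord(ms[inside, 1], range(moving@voxels), bins)
  jh <- .jointHistParzen(fb, pz$coord, bins)
  N <- sum(jh$hist)
  p <- jh$hist / N
  pF <- rowSums(p); pM <- colSums(p)
  nzp <- p > 0
  mi <- sum(p[nzp] * log2(p[nzp] / outer(pF, pM)[nzp]))
  if (valueOnly) return(list(mi = mi))
  # L[f, k] = log2(p / pM) where defined
  pMm <- matrix(pM, bins, bins, byrow = TRUE)
  L <- matrix(0, bins, bins)
  ok <- p > 0 & pMm > 0
  L[ok] <- log2(p[ok] / pMm[ok])
  n <- length(fb)
  # s_i = sum_j L[f_i, k0_i + j] dbeta_ij (4 support bins per sample)
  kcols <- outer(jh$k0, 0:3, "+") + 1L            # 1-based bin columns
  Lrows <- matrix(L[cbind(rep(fb + 1L, 4), as.vector(kcols))], n, 4)
  s <- rowSums(Lrows * jh$dw)
  # dMI/dm_i = s_i / (N * parzen width); chain via the moving gradient (mm)
  gradM <- ms[inside, 2:4, drop = FALSE] /
    matrix(moving@spacing, n, 3, byrow = TRUE)
  alpha <- -(s / (N * pz$width)) * gradM          # gradient of -MI
  list(mi = mi, alpha = alpha, ptsIn = ptsIn, insideFraction = mean(inside))
}

# Parzen-window MI (value and gradient of -MI w.r.t. FFD coefficients)
.parzenEnergy <- function(fixed, moving, affine, ffd, pts, settings,
                          valueOnly = FALSE) {
  mapped <- transformPoints(affine, pts) + ffdDisplacement(ffd, pts)
  pe <- .parzenMIAlpha(fixed, moving, pts, mapped, settings$bins, valueOnly)
  if (valueOnly) return(list(mi = pe$mi))
  miGrad <- .ffdScatter(ffd@gridOrigin, ffd@gridSpacing, ffd@gridSize,
                        pe$ptsIn, pe$alpha)
  list(mi = pe$mi, miGrad = miGrad)
}

.energyGradientFD <- function(fixed, moving, pairs, affine, ffd, omega,
                              settings, pts, eps = 1e-5) {
  evalE <- function(co) {
    f2 <- ffd; f2@coefficients <- co
    ev <- .parzenEnergy(fixed, moving, affine, f2, pts, settings,
                        valueOnly = TRUE)
    E <- -ev$mi
    if (!is.null(pairs) && nrow(pairs) > 0 && omega > 0)
      E <- E + omega * cpPenalty(pairs, compositeTransform(affine, f2))
    E
  }
  co <- ffd@coefficients
  grad <- matrix(0, nrow(co), 3)
  for (k in seq_len(nrow(co))) for (c in 1:3) {
    cp <- co; cp[k, c] <- cp[k, c] + eps
    cm <- co; cm[k, c] <- cm[k, c] - eps
    grad[k, c] <- (evalE(cp) - evalE(cm)) / (2 * eps)
  }
  base <- energyAndGradient(fixed, moving, pairs,
                            compositeTransform(affine, ffd), omega,
                            settings, samplePoints = pts)
  list(E = base$E, gradient = grad, mi = base$mi, cp = base$cp,
       samplePoints = pts)
}
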