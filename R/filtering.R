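#' @useDynLib volreg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# sampled, normalized Gaussian kernel; radius 4 sigma
.gaussKernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# first-derivative-of-Gaussian kernel, normalized by the Gaussian sum so
# that it is the exact derivative of the sampled smoothing kernel
.gaussDerivKernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  (-x / sigma^2) * g / sum(g)
}

# second derivative of Gaussian, same normalization
.gaussDeriv2Kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  ((x^2 - sigma^2) / sigma^4) * g / sum(g)
}

# separable convolution of a raw array with per-axis kernels (NULL = skip)
.convSep <- function(arr, kx = NULL, ky = NULL, kz = NULL) {
  if (!is.null(kx)) arr <- .conv1dReflect(arr, kx, 0L)
  if (!is.null(ky)) arr <- .conv1dReflect(arr, ky, 1L)
  if (!is.null(kz)) arr <- .conv1dReflect(arr, kz, 2L)
  arr
}

#' Gaussian smoothing of a volume
#'
#' Separable convolution with a sampled Gaussian (radius 4 sigma) and
#' half-sample symmetric (reflective) borders, which preserves the mean
#' intensity. Sigma is given per axis in voxels; a zero sigma leaves that
#' axis untouched.
#'
#' @param vol a Volume.
#' @param sigma per-axis standard deviation in voxels (scalar recycled).
#' @return the smoothed Volume on the same grid.
#' @export
gaussianSmooth <- function(vol, sigma) {
  sigma <- rep_len(as.numeric(sigma), 3)
  if (any(!is.finite(sigma)) || any(sigma < 0))
    stop("sigma must be non-negative")
  arr <- vol@voxels
  for (ax in 1:3)
    if (sigma[ax] > 0)
      arr <- .conv1dReflect(arr, .gaussKernel(sigma[ax]), as.integer(ax - 1))
  Volume(arr, vol@spacing, vol@origin)
}

# Gaussian derivative L_a at scale sigmaD (voxels): derivative kernel along
# axis `axis`, plain Gaussian along the others. Returns a raw array.
.gaussDeriv <- function(arr, sigma, axis) {
  sigma <- rep_len(sigma, 3)
  kerns <- lapply(1:3, function(a)
    if (a == axis) .gaussDerivKernel(sigma[a]) else .gaussKernel(sigma[a]))
  .convSep(arr, kerns[[1]], kerns[[2]], kerns[[3]])
}

.gaussDeriv2 <- function(arr, sigma, axis) {
  sigma <- rep_len(sigma, 3)
  kerns <- lapply(1:3, function(a)
    if (a == axis) .gaussDeriv2Kernel(sigma[a]) else .gaussKernel(sigma[a]))
  .convSep(arr, kerns[[1]], kerns[[2]], kerns[[3]])
}

# per-axis sigma in voxels giving physically isotropic smoothing in mm:
# sigma is quoted in voxels of the smallest spacing
.isoSigmaVoxels <- function(sigma, spacing) {
  sigma * min(spacing) / spacing
}

# min-max normalization of a raw array to [0, 1]
.normalize01 <- function(arr) {
  rng <- range(arr)
  if (rng[2] > rng[1]) (arr - rng[1]) / (rng[2] - rng[1])
  else arr * 0
}
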