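# 4096-dimensional volumetric SIFT-style descriptors and ratio-test
# matching. The local window around a keypoint is split into 4 x 4 x 4
# subregions of `patchWidth` voxels; in each subregion the gradient of
# every voxel is accumulated, by magnitude, into an 8 (azimuth) x 8
# (elevation) orientation histogram with trilinear spatial and bilinear
# orientation soft-binning and a Gaussian spatial weight. The concatenated
# vector is normalized to unit length, clamped at 0.2 per entry and
# renormalized, making the final descriptor invariant to affine intensity
# scaling.

#' Compute descriptors at keypoint locations
#'
#' Keypoints whose support window (4 subregions of \code{patchWidth}
#' voxels per axis, plus one voxel for central differences) exits the
#' volume are skipped with \code{skipBorder = TRUE} (the default) or raise
#' an error otherwise. The volume is min-max normalized internally; the
#' descriptor itself is intensity-scale invariant after normalization.
#'
#' @param vol a Volume.
#' @param keypoints data.frame with 0-based index columns ix, iy, iz (from
#'   the detectors); positions are rounded to the nearest voxel.
#' @param patchWidth voxels per subregion side (default 4, giving the
#'   16^3-voxel support of the 4096-dimensional descriptor).
#' @param skipBorder drop keypoints too close to the border instead of
#'   erroring.
#' @return list with \code{keypoints} (the retained rows) and
#'   \code{vectors} (n x 4096 matrix; rows are unit length, or all zero
#'   for gradient-free patches).
#' @export
computeDescriptors <- function(vol, keypoints, patchWidth = 4,
                               skipBorder = TRUE) {
  stopifnot(patchWidth >= 1)
  d <- dim(vol)
  half <- 2 * patchWidth
  ctr <- round(as.matrix(keypoints[, c("ix", "iy", "iz")]))
  ok <- ctr[, 1] - half >= 1 & ctr[, 1] + half - 1 <= d[1] - 2 &
        ctr[, 2] - half >= 1 & ctr[, 2] + half - 1 <= d[2] - 2 &
        ctr[, 3] - half >= 1 & ctr[, 3] + half - 1 <= d[3] - 2
  if (!all(ok)) {
    if (!skipBorder)
      stop("descriptor support window exits the volume for keypoint(s) ",
           paste(utils::head(which(!ok), 5), collapse = ", "))
    keypoints <- keypoints[ok, , drop = FALSE]
    ctr <- ctr[ok, , drop = FALSE]
  }
  if (nrow(keypoints) == 0)
    return(list(keypoints = keypoints,
                vectors = matrix(numeric(0), 0, 4096)))
  arr <- .normalize01(vol@voxels)
  storage.mode(ctr) <- "integer"
  raw <- .siftDescriptors(arr, ctr, as.integer(patchWidth))
  vec <- .normalizeDescriptors(raw)
  list(keypoints = keypoints, vectors = vec)
}

# unit-normalize, clamp entries at 0.2, renormalize (SIFT conditioning);
# all-zero rows stay all-zero
.normalizeDescriptors <- function(m, clamp = 0.2) {
  nrm <- sqrt(rowSums(m^2))
  nz <- nrm > 0
  m[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
  m[m > clamp] <- clamp
  nrm <- sqrt(rowSums(m^2))
  nz <- nrm > 0
  m[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
  m
}

#' Match descriptors between two images with the ratio test
#'
#' For each fixed-image feature \code{u}, the nearest (\code{v}) and
#' second-nearest (\code{v'}) moving-image features by Euclidean descriptor
#' distance are found, and the pair is accepted iff
#' \code{d(u, v) / d(u, v') < t4}. When several fixed features select the
#' same moving feature, only the lowest-ratio match is kept (one-to-one
#' matching; ties break to the lower fixed index). With a single moving
#' feature the ratio is undefined and a pair is accepted, with ratio 0,
#' only on an exact descriptor match.
#'
#' @param fixedFeatures,movingFeatures results of
#'   \code{\link{computeDescriptors}}.
#' @param t4 ratio threshold in (0, 1] (default 0.9).
#' @return data.frame of matched world coordinates \code{xF, yF, zF, xM,
#'   yM, zM} and \code{ratio}, ordered by fixed keypoint index.
#' @export
matchFeatures <- function(fixedFeatures, movingFeatures, t4 = 0.9) {
  stopifnot(t4 > 0, t4 <= 1)
  FV <- fixedFeatures$vectors
  MV <- movingFeatures$vectors
  if (nrow(FV) == 0 || nrow(MV) == 0)
    stop("both feature sets must be non-empty")
  empty <- data.frame(xF = numeric(0), yF = numeric(0), zF = numeric(0),
                      xM = numeric(0), yM = numeric(0), zM = numeric(0),
                      ratio = numeric(0))
  d2 <- outer(rowSums(FV^2), rep(1, nrow(MV))) +
        outer(rep(1, nrow(FV)), rowSums(MV^2)) - 2 * FV %*% t(MV)
  d2[d2 < 1e-12] <- 0     # snap numerically-zero distances (unit vectors)
  dmat <- sqrt(d2)
  if (nrow(MV) == 1) {
    hit <- which(dmat[, 1] == 0)
    if (length(hit) == 0) return(empty)
    best <- rep(1L, length(hit)); ratio <- rep(0, length(hit))
    fidx <- hit
  } else {
    ord <- t(apply(dmat, 1, function(r) order(r)[1:2]))
    d1 <- dmat[cbind(seq_len(nrow(dmat)), ord[, 1])]
    dsec <- dmat[cbind(seq_len(nrow(dmat)), ord[, 2])]
    ratio <- ifelse(dsec > 0, d1 / dsec, ifelse(d1 == 0, 1, Inf))
    acc <- ratio < t4
    if (!any(acc)) return(empty)
    fidx <- which(acc); best <- ord[acc, 1]; ratio <- ratio[acc]
  }
  # one-to-one: keep the lowest-ratio fixed feature per moving feature;
  # ties break to the lower fixed index (stable order)
  keep <- !duplicated(best[order(ratio, fidx)])
  sel <- order(ratio, fidx)[keep]
  sel <- sort(sel)
  fkp <- fixedFeatures$keypoints[fidx[sel], , drop = FALSE]
  mkp <- movingFeatures$keypoints[best[sel], , drop = FALSE]
  data.frame(xF = fkp$x, yF = fkp$y, zF = fkp$z,
             xM = mkp$x, yM = mkp$y, zM = mkp$z, ratio = ratio[sel])
}

#' Read/write correspondence pairs as plain text
#'
#' One line per pair: \code{xF yF zF xM yM zM ratio} (mm, world
#' coordinates); \code{#} comments allowed.
#' @param path file path.
#' @return data.frame as produced by \code{\link{matchFeatures}}.
#' @export
readPairs <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cols <- c("xF", "yF", "zF", "xM", "yM", "zM", "ratio")
  if (length(lines) == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, 7))
    names(out) <- cols
    return(out)
  }
  vals <- t(vapply(strsplit(lines, "\\s+"),
                   function(v) { v <- as.numeric(v); length(v) <- 7; v },
                   numeric(7)))
  out <- as.data.frame(vals)
  names(out) <- cols
  out$ratio[is.na(out$ratio)] <- 0
  out
}

#' @rdname readPairs
#' @param pairs data.frame of correspondences.
#' @export
writePairs <- function(pairs, path) {
  writeLines(sprintf("%.17g %.17g %.17g %.17g %.17g %.17g %.17g",
                     pairs$xF, pairs$yF, pairs$zF,
                     pairs$xM, pairs$yM, pairs$zM, pairs$ratio), path)
  invisible(NULL)
}
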