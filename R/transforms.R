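.asPointMatrix <- function(points) {
  if (is.null(dim(points))) matrix(as.numeric(points), 1, 3)
  else {
    m <- as.matrix(points)
    storage.mode(m) <- "double"
    m
  }
}

#' @rdname transformPoints
setMethod("transformPoints", "AffineTransform", function(transform, points) {
  p <- .asPointMatrix(points)
  ctr <- transform@center
  out <- sweep(p, 2, ctr, "-") %*% t(transform@matrix)
  sweep(out, 2, ctr + transform@translation, "+")
})

#' @rdname transformPoints
setMethod("transformPoints", "FFDTransform", function(transform, points) {
  p <- .asPointMatrix(points)
  p + .ffdDisplace(transform@coefficients, transform@gridOrigin,
                   transform@gridSpacing, transform@gridSize, p)
})

#' @rdname transformPoints
setMethod("transformPoints", "CompositeTransform", function(transform, points) {
  p <- .asPointMatrix(points)
  transformPoints(transform@global, p) +
    .ffdDisplace(transform@local@coefficients, transform@local@gridOrigin,
                 transform@local@gridSpacing, transform@local@gridSize, p)
})

#' FFD displacement field evaluated at points
#'
#' @param ffd an FFDTransform.
#' @param points n x 3 world coordinates (mm).
#' @return n x 3 displacement matrix (mm).
#' @export
ffdDisplacement <- function(ffd, points) {
  p <- .asPointMatrix(points)
  .ffdDisplace(ffd@coefficients, ffd@gridOrigin, ffd@gridSpacing,
               ffd@gridSize, p)
}

#' Jacobian of an FFD with respect to its control-point displacements
#'
#' For each point, the nonzero partial derivatives of \code{T(x)} with
#' respect to the control-point displacement vectors: the tensor-product
#' cubic B-spline weight of each of the 64 supporting control points. The
#' weight is identical for the three displacement components. Rows per
#' point sum to 1 (partition of unity).
#'
#' @param ffd an FFDTransform.
#' @param points n x 3 world coordinates (mm), inside the valid grid domain.
#' @return data.frame with columns \code{point} (1-based row of
#'   \code{points}), \code{cp} (1-based control-point index, x-fastest) and
#'   \code{weight}.
#' @export
transformJacobian <- function(ffd, points) {
  p <- .asPointMatrix(points)
  tr <- .ffdJacobian(ffd@gridOrigin, ffd@gridSpacing, ffd@gridSize, p)
  data.frame(point = as.integer(tr[, 1]) + 1L,
             cp = as.integer(tr[, 2]) + 1L, weight = tr[, 3])
}

#' Build an FFD lattice covering a volume's world extent
#'
#' Control points are laid out with uniform spacing starting one spacing
#' before the domain minimum, with enough points that the cubic support of
#' every domain point stays inside the lattice.
#'
#' @param vol Volume whose world extent must be covered.
#' @param gridSpacing control-point spacing in mm (scalar or per-axis).
#' @return an identity FFDTransform (zero coefficients).
#' @export
ffdGrid <- function(vol, gridSpacing) {
  gridSpacing <- rep_len(as.numeric(gridSpacing), 3)
  d <- dim(vol@voxels)
  extent <- (d - 1) * vol@spacing
  if (any(gridSpacing > extent))
    stop("grid spacing larger than domain extent")
  wmin <- vol@origin
  # need t(xmax) <= K - 2 with t = (x - o)/h, o = wmin - h
  K <- ceiling(extent / gridSpacing - 1e-9) + 4L
  K <- pmax(K, 4L)
  ffdTransform(gridOrigin = wmin - gridSpacing, gridSpacing = gridSpacing,
               gridSize = K)
}

#' Dyadic refinement of an FFD
#'
#' Halves the control-point spacing using the exact cubic B-spline
#' subdivision rules, reproducing the displacement field over the original
#' domain to machine precision. Even-index rule
#' \code{(c[i-1] + 6 c[i] + c[i+1]) / 8}, odd-index rule
#' \code{(c[i] + c[i+1]) / 2}, applied per axis.
#'
#' @param ffd an FFDTransform.
#' @return an FFDTransform with spacing halved and grid size 2K - 1.
#' @export
refineFFD <- function(ffd) {
  K <- ffd@gridSize
  co <- array(ffd@coefficients, c(K, 3))
  # pad one zero ring so boundary rules see zeros beyond the lattice
  Kp <- K + 2L
  pad <- array(0, c(Kp, 3))
  pad[2:(K[1] + 1), 2:(K[2] + 1), 2:(K[3] + 1), ] <- co
  for (ax in 1:3) {
    n <- dim(pad)[ax]
    nf <- 2L * (n - 2L) - 1L        # fine points spanning original lattice
    dimsOut <- dim(pad); dimsOut[ax] <- nf
    out <- array(0, dimsOut)
    idxC <- function(i) .sliceAxis(pad, ax, i)
    for (j in seq_len(nf)) {
      # fine index j (1-based) at coarse position (j-1)/2 over unpadded grid
      i <- (j - 1L) %/% 2L + 2L     # coarse index in padded coords
      sl <- if ((j - 1L) %% 2L == 0L)
        (idxC(i - 1L) + 6 * idxC(i) + idxC(i + 1L)) / 8
      else
        (idxC(i) + idxC(i + 1L)) / 2
      out <- .assignSlice(out, ax, j, sl)
    }
    pad <- out
  }
  Kf <- 2L * K - 1L
  ffdTransform(gridOrigin = ffd@gridOrigin,
               gridSpacing = ffd@gridSpacing / 2,
               gridSize = Kf,
               coefficients = matrix(pad, prod(Kf), 3))
}

.sliceAxis <- function(arr, ax, i) {
  switch(ax, arr[i, , , , drop = FALSE], arr[, i, , , drop = FALSE],
         arr[, , i, , drop = FALSE])
}

.assignSlice <- function(arr, ax, i, val) {
  switch(ax,
         { arr[i, , , ] <- val; arr },
         { arr[, i, , ] <- val; arr },
         { arr[, , i, ] <- val; arr })
}

# ---- serialization ----

#' Write a transform to a plain-text file
#'
#' Format: a \code{kind} line (\code{affine}, \code{ffd} or
#' \code{composite}), then for an affine the 12 numbers (row-major matrix,
#' translation, center), and for an FFD a grid header (origin, spacing,
#' size) followed by one \code{dx dy dz} line per control point in
#' x-fastest order. Round-trips exactly.
#'
#' @param transform Affine/FFD/CompositeTransform.
#' @param path output path.
#' @export
writeTransform <- function(transform, path) {
  con <- file(path, "w")
  on.exit(close(con))
  .writeTransformCon(transform, con)
  invisible(NULL)
}

.writeTransformCon <- function(transform, con) {
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  if (is(transform, "AffineTransform")) {
    writeLines("kind affine", con)
    writeLines(fmt(t(transform@matrix)), con)
    writeLines(fmt(transform@translation), con)
    writeLines(fmt(transform@center), con)
  } else if (is(transform, "FFDTransform")) {
    writeLines("kind ffd", con)
    writeLines(paste("origin", fmt(transform@gridOrigin)), con)
    writeLines(paste("spacing", fmt(transform@gridSpacing)), con)
    writeLines(paste("size", paste(transform@gridSize, collapse = " ")), con)
    co <- transform@coefficients
    writeLines(sprintf("%.17g %.17g %.17g", co[, 1], co[, 2], co[, 3]), con)
  } else if (is(transform, "CompositeTransform")) {
    writeLines("kind composite", con)
    .writeTransformCon(transform@global, con)
    .writeTransformCon(transform@local, con)
  } else stop("unsupported transform class: ", class(transform))
}

#' Read a transform written by \code{writeTransform}
#' @param path file path.
#' @return the transform object.
#' @export
readTransform <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  res <- .parseTransform(lines, 1)
  res$transform
}

.parseTransform <- function(lines, i) {
  header <- strsplit(lines[i], "\\s+")[[1]]
  if (header[1] != "kind") stop("expected 'kind' line in transform file")
  kind <- header[2]
  nums <- function(s) as.numeric(strsplit(s, "\\s+")[[1]])
  if (kind == "affine") {
    m <- matrix(nums(lines[i + 1]), 3, 3, byrow = TRUE)
    list(transform = affineTransform(m, nums(lines[i + 2]),
                                     nums(lines[i + 3])), next_ = i + 4)
  } else if (kind == "ffd") {
    org <- nums(sub("^origin\\s+", "", lines[i + 1]))
    sp <- nums(sub("^spacing\\s+", "", lines[i + 2]))
    sz <- as.integer(nums(sub("^size\\s+", "", lines[i + 3])))
    K <- prod(sz)
    co <- t(vapply(lines[(i + 4):(i + 3 + K)], nums, numeric(3)))
    dimnames(co) <- NULL
    list(transform = ffdTransform(org, sp, sz, co), next_ = i + 4 + K)
  } else if (kind == "composite") {
    g <- .parseTransform(lines, i + 1)
    l <- .parseTransform(lines, g$next_)
    list(transform = compositeTransform(g$transform, l$transform),
         next_ = l$next_)
  } else stop("unknown transform kind: ", kind)
}
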