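#' Read a 3D volume from NIfTI or MetaImage
#'
#' Supports NIfTI-1 (\code{.nii}, \code{.nii.gz}) through RNifti and
#' MetaImage (\code{.mha}, \code{.mhd} + raw). Only axis-aligned grids are
#' accepted: a file whose direction matrix is not the identity is rejected.
#'
#' @param path file path.
#' @param labels if TRUE, return a \code{LabelMap} (integer voxels) with
#'   \code{legend}.
#' @param legend label legend used when \code{labels = TRUE}.
#' @return a \code{Volume} or \code{LabelMap}.
#' @export
readVolume <- function(path, labels = FALSE, legend = cardiacLegend()) {
  if (!file.exists(path))
    stop("file does not exist: ", path)
  ext <- tolower(sub("^.*?(\\.[a-zA-Z]+(\\.gz)?)$", "\\1", basename(path)))
  if (ext %in% c(".nii", ".nii.gz", ".gz")) {
    vol <- .readNifti(path)
  } else if (ext %in% c(".mha", ".mhd")) {
    vol <- .readMetaImage(path)
  } else {
    stop("unsupported volume format: ", path)
  }
  if (labels)
    LabelMap(vol@voxels, vol@spacing, vol@origin, legend = legend)
  else vol
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' The format is chosen from the file extension. Voxel values and grid
#' metadata round-trip exactly through \code{readVolume}. LabelMaps are
#' written with an integer element type.
#'
#' @param vol a Volume or LabelMap.
#' @param path output path ending in .nii, .nii.gz, .mha or .mhd.
#' @export
writeVolume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  ext <- tolower(sub("^.*?(\\.[a-zA-Z]+(\\.gz)?)$", "\\1", basename(path)))
  isLabel <- is(vol, "LabelMap")
  if (ext %in% c(".nii", ".nii.gz", ".gz")) {
    .writeNifti(vol, path, integer = isLabel)
  } else if (ext %in% c(".mha", ".mhd")) {
    .writeMetaImage(vol, path, integer = isLabel)
  } else {
    stop("unsupported volume format: ", path)
  }
  invisible(NULL)
}

.readNifti <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file ", path,
                                           ": ", conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) != 3)
    stop("expected a 3D NIfTI volume: ", path)
  xfm <- RNifti::xform(img)
  sp <- sqrt(colSums(xfm[1:3, 1:3]^2))
  dirn <- sweep(xfm[1:3, 1:3], 2, sp, "/")
  if (max(abs(dirn - diag(3))) > 1e-4)
    stop("non-axis-aligned NIfTI direction matrix not supported: ", path)
  Volume(array(as.numeric(arr), dim(arr)), spacing = sp,
         origin = as.numeric(xfm[1:3, 4]))
}

.writeNifti <- function(vol, path, integer = FALSE) {
  arr <- vol@voxels
  storage.mode(arr) <- if (integer) "integer" else "double"
  img <- RNifti::asNifti(arr)
  h <- RNifti::niftiHeader(img)
  h$pixdim[2:4] <- vol@spacing
  h$srow_x <- c(vol@spacing[1], 0, 0, vol@origin[1])
  h$srow_y <- c(0, vol@spacing[2], 0, vol@origin[2])
  h$srow_z <- c(0, 0, vol@spacing[3], vol@origin[3])
  h$sform_code <- 2L
  h$qform_code <- 0L
  img <- RNifti::asNifti(arr, reference = h)
  RNifti::writeNifti(img, path, datatype = if (integer) "int32" else "double")
}

# ---- MetaImage (.mha local, .mhd + raw) ----

.metaTypes <- c(MET_UCHAR = "uint8", MET_CHAR = "int8", MET_SHORT = "int16",
                MET_USHORT = "uint16", MET_INT = "int32", MET_UINT = "uint32",
                MET_FLOAT = "float32", MET_DOUBLE = "float64")

.readMetaImage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list(); dataFile <- NULL
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0)
      stop("truncated MetaImage header: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed MetaImage header line in ", path)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") { dataFile <- val; break }
  }
  ndims <- as.integer(hdr[["NDims"]])
  if (is.na(ndims) || ndims != 3)
    stop("only 3D MetaImage supported: ", path)
  size <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  sp <- if (!is.null(hdr[["ElementSpacing"]]))
    as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]]) else c(1, 1, 1)
  org <- if (!is.null(hdr[["Offset"]]))
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]])
  else if (!is.null(hdr[["Position"]]))
    as.numeric(strsplit(hdr[["Position"]], "\\s+")[[1]]) else c(0, 0, 0)
  if (!is.null(hdr[["TransformMatrix"]])) {
    tm <- matrix(as.numeric(strsplit(hdr[["TransformMatrix"]], "\\s+")[[1]]),
                 3, 3, byrow = TRUE)
    if (max(abs(tm - diag(3))) > 1e-6)
      stop("non-identity MetaImage TransformMatrix not supported: ", path)
  }
  et <- hdr[["ElementType"]]
  if (is.null(et) || !(et %in% names(.metaTypes)))
    stop("unsupported MetaImage ElementType in ", path)
  msb <- identical(hdr[["ElementByteOrderMSB"]], "True") ||
         identical(hdr[["BinaryDataByteOrderMSB"]], "True")
  compressed <- identical(hdr[["CompressedData"]], "True")
  n <- prod(size)
  bytesPer <- c(uint8 = 1, int8 = 1, int16 = 2, uint16 = 2, int32 = 4,
                uint32 = 4, float32 = 4, float64 = 8)[[.metaTypes[[et]]]]
  if (identical(dataFile, "LOCAL")) {
    raw <- readBin(con, "raw", n = if (compressed) 2^31 - 1 else n * bytesPer)
  } else {
    rawPath <- file.path(dirname(path), dataFile)
    if (!file.exists(rawPath))
      stop("MetaImage data file missing: ", rawPath)
    raw <- readBin(rawPath, "raw", n = file.info(rawPath)$size)
  }
  if (compressed)
    raw <- memDecompress(raw, type = "gzip")
  if (length(raw) < n * bytesPer)
    stop("truncated MetaImage data in ", path)
  vals <- .decodeRaw(raw, .metaTypes[[et]], n, msb)
  Volume(array(vals, size), spacing = sp, origin = org)
}

.decodeRaw <- function(raw, type, n, msb) {
  endian <- if (msb) "big" else "little"
  switch(type,
    uint8  = as.numeric(readBin(raw, "integer", n, size = 1, signed = FALSE)),
    int8   = as.numeric(readBin(raw, "integer", n, size = 1, signed = TRUE)),
    int16  = as.numeric(readBin(raw, "integer", n, size = 2, signed = TRUE,
                                endian = endian)),
    uint16 = as.numeric(readBin(raw, "integer", n, size = 2, signed = FALSE,
                                endian = endian)),
    int32  = as.numeric(readBin(raw, "integer", n, size = 4, endian = endian)),
    uint32 = {
      v <- readBin(raw, "integer", n, size = 4, endian = endian)
      ifelse(v < 0, v + 2^32, as.numeric(v))
    },
    float32 = as.numeric(readBin(raw, "double", n, size = 4, endian = endian)),
    float64 = readBin(raw, "double", n, size = 8, endian = endian))
}

.writeMetaImage <- function(vol, path, integer = FALSE) {
  size <- dim(vol@voxels)
  et <- if (integer) "MET_INT" else "MET_DOUBLE"
  local <- grepl("\\.mha$", path, ignore.case = TRUE)
  dataFile <- if (local) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path),
                                                 ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %.17g %.17g %.17g", vol@origin[1], vol@origin[2],
            vol@origin[3]),
    sprintf("ElementSpacing = %.17g %.17g %.17g", vol@spacing[1],
            vol@spacing[2], vol@spacing[3]),
    sprintf("DimSize = %d %d %d", size[1], size[2], size[3]),
    sprintf("ElementType = %s", et),
    sprintf("ElementDataFile = %s", dataFile))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write ", path))
  writeLines(hdr, con)
  if (local) {
    .encodeRaw(vol@voxels, integer, con)
    close(con)
  } else {
    close(con)
    rcon <- file(file.path(dirname(path), dataFile), "wb")
    .encodeRaw(vol@voxels, integer, rcon)
    close(rcon)
  }
}

.encodeRaw <- function(arr, integer, con) {
  if (integer) writeBin(as.integer(arr), con, size = 4, endian = "little")
  else writeBin(as.numeric(arr), con, size = 8, endian = "little")
}

# ---- point sets ----

#' Read a point set from plain text
#'
#' One \code{x y z} world-coordinate triple (mm) per line; \code{#} starts a
#' comment. Order is significant (index aligns corresponding sets).
#' @param path file path.
#' @return n x 3 numeric matrix.
#' @export
readPointSet <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(matrix(numeric(0), 0, 3))
  vals <- lapply(strsplit(lines, "\\s+"), as.numeric)
  if (any(vapply(vals, length, 1L) < 3))
    stop("point-set lines must have at least 3 numbers: ", path)
  pts <- t(vapply(vals, function(v) v[1:3], numeric(3)))
  if (any(!is.finite(pts))) stop("non-finite coordinates in ", path)
  pts
}

#' Write a point set as plain text
#' @param points n x 3 matrix of world coordinates (mm).
#' @param path output path.
#' @export
writePointSet <- function(points, path) {
  points <- as.matrix(points)
  writeLines(sprintf("%.17g %.17g %.17g", points[, 1], points[, 2],
                     points[, 3]), path)
  invisible(NULL)
}

# ---- world <-> index geometry ----

#' Convert between continuous voxel indices and world coordinates
#'
#' Indices are 0-based and may be non-integer; \code{world = origin +
#' index * spacing}. Out-of-grid points are legal.
#'
#' @param vol a Volume supplying the grid.
#' @param coords n x 3 matrix or length-3 vector.
#' @return n x 3 matrix (or vector, matching the input shape).
#' @export
indexToWorld <- function(vol, coords) {
  .gridAffine(coords, vol@origin, vol@spacing, toWorld = TRUE)
}

#' @rdname indexToWorld
#' @export
worldToIndex <- function(vol, coords) {
  .gridAffine(coords, vol@origin, vol@spacing, toWorld = FALSE)
}

.gridAffine <- function(coords, origin, spacing, toWorld) {
  vec <- is.null(dim(coords))
  m <- if (vec) matrix(coords, 1, 3) else as.matrix(coords)
  if (any(!is.finite(m))) stop("coordinates must be finite")
  out <- if (toWorld)
    sweep(sweep(m, 2, spacing, "*"), 2, origin, "+")
  else
    sweep(sweep(m, 2, origin, "-"), 2, spacing, "/")
  if (vec) as.numeric(out) else out
}
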