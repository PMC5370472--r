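test_that("volume I/O round-trips bit-for-bit in both formats", {
  v <- randomVolume(8, seed = 3, spacing = c(0.348, 0.348, 0.5),
                    origin = c(10, -5, 2.5))
  for (ext in c(".nii.gz", ".nii", ".mha", ".mhd")) {
    f <- tempfile(fileext = ext)
    writeVolume(v, f)
    v2 <- readVolume(f)
    expect_identical(v2@voxels, v@voxels, label = ext)
    # NIfTI-1 stores grid geometry in single precision; the MetaImage
    # writer uses full-precision ASCII
    tol <- if (grepl("nii", ext)) 1e-6 else 1e-12
    expect_equal(v2@spacing, v@spacing, tolerance = tol)
    expect_equal(v2@origin, v@origin, tolerance = tol)
  }
})

test_that("label maps round-trip with integer values preserved exactly", {
  lab <- LabelMap(array(sample(0:6, 64, replace = TRUE), c(4, 4, 4)))
  for (ext in c(".nii.gz", ".mha")) {
    f <- tempfile(fileext = ext)
    writeVolume(lab, f)
    back <- readVolume(f, labels = TRUE)
    expect_identical(back@voxels, lab@voxels)
  }
})

test_that("I/O error paths are informative", {
  expect_error(readVolume(tempfile(fileext = ".nii")), "exist")
  u <- tempfile(fileext = ".xyz"); writeLines("x", u)
  expect_error(readVolume(u), "unsupported")
  f <- tempfile(fileext = ".mha")
  writeLines("ObjectType = Image", f)   # truncated header
  expect_error(readVolume(f), "MetaImage")
  g <- tempfile(fileext = ".nii")
  writeBin(as.raw(1:64), g)             # garbled content
  expect_error(readVolume(g), "NIfTI")
  v <- randomVolume(4)
  expect_error(writeVolume(v, file.path(tempdir(), "noexist", "a.nii")),
               "directory")
  expect_error(writeVolume(v, tempfile(fileext = ".foo")), "unsupported")
})

test_that("world/index conversion follows the affine grid formula", {
  v <- Volume(array(0, c(4, 4, 4)), spacing = c(0.348, 0.348, 0.5),
              origin = c(10, 0, 0))
  expect_equal(indexToWorld(v, c(0, 0, 0)), c(10, 0, 0))
  expect_equal(worldToIndex(v, c(10.348, 0.348, 0.5)), c(1, 1, 1),
               tolerance = 1e-12)
  set.seed(1)
  idx <- matrix(runif(30, -2, 6), 10, 3)   # off-grid indices are legal
  expect_equal(worldToIndex(v, indexToWorld(v, idx)), idx,
               tolerance = 1e-9)
  expect_error(worldToIndex(v, c(1, NA, 2)), "finite")
})

test_that("gaussian smoothing: identity, flat-field and closed-form impulse", {
  v <- randomVolume(12, seed = 5)
  expect_identical(gaussianSmooth(v, 0)@voxels, v@voxels)
  flat <- Volume(array(3.7, c(10, 10, 10)))
  expect_equal(gaussianSmooth(flat, 2)@voxels, flat@voxels,
               tolerance = 1e-12)
  # delta impulse -> sampled separable Gaussian kernel
  n <- 33
  d <- array(0, c(n, n, n)); d[17, 17, 17] <- 1
  sm <- gaussianSmooth(Volume(d), 2)
  r <- max(1, ceiling(4 * 2)); x <- (-r):r
  k <- exp(-x^2 / 8); k <- k / sum(k)
  expected <- outer(outer(k, k), k)
  got <- sm@voxels[17 + x, 17 + x, 17 + x]
  expect_equal(got, expected, tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(gaussianSmooth(v, c(-1, 0, 0)), "non-negative")
})

test_that("gaussian smoothing preserves the mean with reflective borders", {
  v <- randomVolume(16, seed = 9)
  s <- gaussianSmooth(v, c(3, 2, 1.5))
  expect_equal(mean(s@voxels), mean(v@voxels), tolerance = 1e-6)
})

test_that("resample: identity no-op, exact one-voxel shift, label rules", {
  v <- randomVolume(8, seed = 2)
  expect_equal(resample(v)@voxels, v@voxels, tolerance = 1e-12)
  # hand-built 5^3: translation by exactly one voxel along x
  h <- Volume(array(seq_len(125), c(5, 5, 5)))
  shifted <- resample(h, affineTransform(translation = c(1, 0, 0)),
                      default = -1)
  expect_equal(shifted@voxels[1:4, , ], h@voxels[2:5, , ])
  expect_true(all(shifted@voxels[5, , ] == -1))
  lab <- LabelMap(array(sample(0:6, 125, TRUE), c(5, 5, 5)))
  out <- resample(lab)
  expect_identical(table(out@voxels), table(lab@voxels))
  expect_s4_class(out, "LabelMap")
  expect_error(resample(lab, interpolation = "linear"), "nearest")
})

test_that("point sets round-trip through the text format", {
  pts <- matrix(c(1.25, -3, 0.5, 10, 20, 30), 2, 3, byrow = TRUE)
  f <- tempfile(fileext = ".txt")
  writePointSet(pts, f)
  cat("# a comment\n", file = f, append = TRUE)
  expect_equal(readPointSet(f), pts, ignore_attr = TRUE)
})

test_that("non-axis-aligned volumes are rejected", {
  f <- tempfile(fileext = ".mha")
  con <- file(f, "wb")
  writeLines(c("ObjectType = Image", "NDims = 3", "BinaryData = True",
               "TransformMatrix = 0 1 0 -1 0 0 0 0 1",
               "DimSize = 2 2 2", "ElementType = MET_DOUBLE",
               "ElementDataFile = LOCAL"), con)
  writeBin(as.numeric(1:8), con, size = 8, endian = "little")
  close(con)
  expect_error(readVolume(f), "axis-aligned|identity")
})
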