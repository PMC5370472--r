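test_that("harris response: flat field, ramp and rank deficiency", {
  flat <- Volume(array(1, c(16, 16, 16)))
  expect_equal(max(abs(harrisResponse(flat, 2, 1.4)@voxels)), 0,
               tolerance = 1e-12)
  # pure 1D ramp: rank-1 autocorrelation, det = 0, response <= 0
  ramp <- Volume(array(rep(seq(0, 1, length.out = 24), 24 * 24),
                       c(24, 24, 24)))
  r <- harrisResponse(ramp, 2, 1.4, alpha = 0.006)
  interior <- r@voxels[8:16, 8:16, 8:16]
  expect_true(all(interior <= 1e-12))
})

test_that("harris response matches a loop-based evaluation at random voxels", {
  set.seed(11)
  n <- 24
  v <- Volume(array(rnorm(n^3), c(n, n, n)))
  sigmaI <- 2; sigmaD <- 1.4; alpha <- 0.006
  got <- harrisResponse(v, sigmaI, sigmaD, alpha)@voxels
  g <- volreg:::.gaussKernel
  gd <- volreg:::.gaussDerivKernel
  kI <- g(sigmaI); kD <- g(sigmaD); kDd <- gd(sigmaD)
  # derivative volumes via the package, then an independent loop-based
  # smoothing + response assembly at sampled voxels
  Lx <- volreg:::.gaussDeriv(v@voxels, rep(sigmaD, 3), 1)
  Ly <- volreg:::.gaussDeriv(v@voxels, rep(sigmaD, 3), 2)
  Lz <- volreg:::.gaussDeriv(v@voxels, rep(sigmaD, 3), 3)
  # oracle for one derivative as well (kernel definition cross-check)
  at0 <- c(12, 13, 11)
  expect_equal(Lx[at0[1], at0[2], at0[3]],
               oracleConvAt(v@voxels, kDd, kD, kD, at0), tolerance = 1e-10)
  prods <- list(xx = Lx * Lx, yy = Ly * Ly, zz = Lz * Lz,
                xy = Lx * Ly, xz = Lx * Lz, yz = Ly * Lz)
  pts <- cbind(sample(5:20, 100, TRUE), sample(5:20, 100, TRUE),
               sample(5:20, 100, TRUE))
  for (i in sample(100, 25)) {     # loop oracle is O(kernel^3) per voxel
    at <- pts[i, ]
    W <- sapply(prods, function(p)
      sigmaD^2 * oracleConvAt(p, kI, kI, kI, at))
    H <- matrix(c(W["xx"], W["xy"], W["xz"],
                  W["xy"], W["yy"], W["yz"],
                  W["xz"], W["yz"], W["zz"]), 3, 3)
    expected <- det(H) - alpha * sum(diag(H))^3
    expect_equal(got[at[1], at[2], at[3]], expected, tolerance = 1e-6)
  }
})

test_that("multi-scale harris finds cube corners and nothing on faces", {
  cube <- cubeVolume(48, 17, 32)
  # a corner voxel outranks a face-centre voxel in the raw response
  resp <- harrisResponse(cube$vol, 2, 1.4, alpha = 0.006)@voxels
  expect_gt(resp[17, 17, 17], resp[24, 24, 17])
  prm <- harrisParams(sigmaIList = 1.4^(0:4))
  kp <- detectHarris(cube$vol, prm)
  expect_gt(nrow(kp), 0)
  kpIdx <- as.matrix(kp[, c("ix", "iy", "iz")])
  dCorner <- volreg:::.minDistances(cube$corners, kpIdx)
  expect_true(all(dCorner <= 2))           # every corner localized
  # no keypoint near a face centre or edge midpoint (>= 8 voxels from any
  # corner); all detections live in the corner regions
  dKp <- volreg:::.minDistances(kpIdx, cube$corners)
  expect_true(all(dKp < 8))
  # determinism
  kp2 <- detectHarris(cube$vol, prm)
  expect_identical(kp, kp2)
  # flat input yields nothing
  expect_identical(nrow(detectHarris(Volume(array(1, c(32, 32, 32))), prm)),
                   0L)
  expect_error(detectHarris(cube$vol, harrisParams(sigmaIList = c(1, 2))),
               "3")
})

test_that("DoG pyramid geometry and constant/impulse behaviour", {
  flat <- Volume(array(2, c(64, 64, 64)))
  pyr <- buildDoGPyramid(flat, dogParams(levels = 3))
  expect_identical(vapply(pyr$levels, function(l) dim(l$base)[1], 1),
                   c(64, 32, 16))
  for (l in pyr$levels)
    for (d in l$dog) expect_equal(max(abs(d@voxels)), 0, tolerance = 1e-12)
  # delta impulse: centre DoG value equals the difference of the two
  # sampled Gaussian kernels' central weights
  n <- 33
  imp <- array(0, c(n, n, n)); imp[17, 17, 17] <- 1
  p <- dogParams(levels = 1, blurSigma = 1.5, scalesPerLevel = 5)
  pyr2 <- buildDoGPyramid(Volume(imp), p)
  k <- 2^(1 / 3)   # ladder ratio for scalesPerLevel = 5
  centreWeight <- function(s) {
    r <- max(1, ceiling(4 * s)); x <- (-r):r
    w <- exp(-x^2 / (2 * s^2)); w <- w / sum(w)
    w[r + 1]^3
  }
  for (j in 1:5) {
    s1 <- 1.5 * k^(j - 1); s2 <- 1.5 * k^j
    expect_equal(pyr2$levels[[1]]$dog[[j]]@voxels[17, 17, 17],
                 centreWeight(s2) - centreWeight(s1), tolerance = 1e-6)
  }
  expect_error(buildDoGPyramid(Volume(array(0, c(16, 16, 16))),
                               dogParams(levels = 3)), "small")
})

test_that("DoG extrema find a planted blob and obey the threshold", {
  v <- blobVolume(48, sigma = 3, ctr = c(24, 24, 24))
  pyr <- buildDoGPyramid(v, dogParams())
  kp <- detectDoGExtrema(pyr)
  expect_gt(nrow(kp), 0)
  strongest <- kp[which.max(abs(kp$response)), ]
  expect_lte(sqrt(sum((c(strongest$ix, strongest$iy, strongest$iz) -
                       c(23, 23, 23))^2)), 2)
  expect_identical(nrow(detectDoGExtrema(pyr, t3 = Inf)), 0L)
  flatP <- buildDoGPyramid(Volume(array(0.5, c(48, 48, 48))), dogParams())
  expect_identical(nrow(detectDoGExtrema(flatP)), 0L)
})

test_that("raising a detection threshold never adds keypoints", {
  rc <- smallCase(seed = 12, maxDisp = 0, noiseSd = 2)
  v <- rc$fixed
  pyr <- buildDoGPyramid(v, dogParams())
  n1 <- nrow(detectDoGExtrema(pyr, t3 = 0.0075))
  n2 <- nrow(detectDoGExtrema(pyr, t3 = 0.02))
  expect_lte(n2, n1)
  p1 <- detectHarris(v, harrisParams(sigmaIList = 1.4^(0:4), t1 = 0.1))
  p2 <- detectHarris(v, harrisParams(sigmaIList = 1.4^(0:4), t1 = 0.3))
  expect_lte(nrow(p2), nrow(p1))
})

test_that("both detectors are translation-equivariant for integer shifts", {
  ph <- makeHeartPhantom(c(48, 48, 48), noiseSd = 0, seed = 13)
  v <- ph$volume
  # the shift is a multiple of every pyramid decimation factor so the
  # translated volume has an exact counterpart at each DoG level
  t <- c(4, -4, 4)
  shifted <- resample(v, affineTransform(translation = t))  # s(x) = v(x + t)
  prm <- harrisParams(sigmaIList = 1.4^(0:4))
  for (det in c("harris", "dog")) {
    kpA <- if (det == "harris") detectHarris(v, prm)
           else detectDoGExtrema(buildDoGPyramid(v, dogParams()))
    kpB <- if (det == "harris") detectHarris(shifted, prm)
           else detectDoGExtrema(buildDoGPyramid(shifted, dogParams()))
    a <- as.matrix(kpA[, c("ix", "iy", "iz")])
    b <- as.matrix(kpB[, c("ix", "iy", "iz")])
    # compare away from the borders, where the shift wraps support
    m <- 10
    interior <- function(x) x[x[, 1] > m & x[, 1] < 47 - m &
                              x[, 2] > m & x[, 2] < 47 - m &
                              x[, 3] > m & x[, 3] < 47 - m, , drop = FALSE]
    ai <- interior(sweep(a, 2, t))   # shifted detections expected here
    expect_gt(nrow(ai), 0, label = det)
    d <- volreg:::.minDistances(ai, b)
    expect_lte(max(d), 1, label = det)
  }
})

test_that("keypoints are re-detected under moderate noise", {
  ph0 <- makeHeartPhantom(c(48, 48, 48), noiseSd = 0, seed = 14)
  # 2% of the intensity range (~80 units)
  ph1 <- makeHeartPhantom(c(48, 48, 48), noiseSd = 1.6, seed = 14)
  k0 <- detectKeypoints(ph0$volume, harrisParams(sigmaIList = 1.4^(0:4)),
                        dogParams())
  k1 <- detectKeypoints(ph1$volume, harrisParams(sigmaIList = 1.4^(0:4)),
                        dogParams())
  expect_gt(nrow(k0), 0)
  d <- volreg:::.minDistances(as.matrix(k0[, c("ix", "iy", "iz")]),
                              as.matrix(k1[, c("ix", "iy", "iz")]))
  expect_gte(mean(d <= 2), 0.7)
})
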