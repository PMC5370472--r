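test_that("affine and FFD point mapping follow the closed forms", {
  expect_equal(transformPoints(affineTransform(), c(1, 2, 3)),
               matrix(c(1, 2, 3), 1), ignore_attr = TRUE)
  aff <- affineTransform(matrix = diag(c(2, 1, 1)),
                         translation = c(0, 5, 0), center = c(10, 0, 0))
  expect_equal(as.numeric(transformPoints(aff, c(12, 0, 0))),
               c(14, 5, 0))
  # uniform coefficients: exact uniform translation (partition of unity)
  dom <- Volume(array(0, c(32, 32, 32)))
  ffd <- ffdGrid(dom, 8)
  ffd@coefficients[, 1] <- 1
  set.seed(31)
  pts <- matrix(runif(3000, 2, 29), 1000, 3)
  disp <- ffdDisplacement(ffd, pts)
  expect_lt(max(abs(disp[, 1] - 1)), 1e-9)
  expect_lt(max(abs(disp[, 2:3])), 1e-9)
  # single control point at a grid node: central weight (2/3)^3
  ffd2 <- ffdGrid(dom, 8)
  K <- ffd2@gridSize
  nodeIdx <- c(3, 3, 3)  # 1-based lattice index
  lin <- nodeIdx[1] + (nodeIdx[2] - 1) * K[1] +
         (nodeIdx[3] - 1) * K[1] * K[2]
  ffd2@coefficients[lin, 2] <- 1
  node <- ffd2@gridOrigin + (nodeIdx - 1) * ffd2@gridSpacing
  expect_equal(as.numeric(ffdDisplacement(ffd2, node)),
               c(0, (2 / 3)^3, 0), tolerance = 1e-12)
})

test_that("FFD jacobian: partition of unity, self-weight, FD agreement", {
  dom <- Volume(array(0, c(32, 32, 32)))
  ffd <- ffdGrid(dom, 8)
  set.seed(32)
  ffd@coefficients <- matrix(rnorm(nrow(ffd@coefficients) * 3, 0, 0.5),
                             ncol = 3)
  pts <- matrix(runif(30, 4, 27), 10, 3)
  J <- transformJacobian(ffd, pts)
  sums <- tapply(J$weight, J$point, sum)
  expect_lt(max(abs(sums - 1)), 1e-12)
  # at a grid node the node's own weight is (2/3)^3
  K <- ffd@gridSize
  node <- ffd@gridOrigin + c(2, 2, 2) * ffd@gridSpacing
  Jn <- transformJacobian(ffd, node)
  lin <- 3 + 2 * K[1] + 2 * K[1] * K[2]
  expect_equal(Jn$weight[Jn$cp == lin], (2 / 3)^3, tolerance = 1e-12)
  # perturbing one coefficient moves T(x) by eps * weight
  eps <- 1e-4
  rows <- which(J$weight > 1e-3)   # avoid FD roundoff on negligible weights
  for (r in sample(rows, 10)) {
    p <- pts[J$point[r], , drop = FALSE]
    f2 <- ffd
    f2@coefficients[J$cp[r], 1] <- f2@coefficients[J$cp[r], 1] + eps
    delta <- ffdDisplacement(f2, p) - ffdDisplacement(ffd, p)
    expect_equal(delta[1, 1], eps * J$weight[r], tolerance = 1e-6)
  }
  expect_error(transformJacobian(ffd, matrix(c(-50, 0, 0), 1)), "domain")
})

test_that("dyadic refinement reproduces the displacement field", {
  dom <- Volume(array(0, c(48, 48, 48)))
  ffd <- makeRandomFFD(dom, 16, 5, seed = 33)
  fine <- refineFFD(ffd)
  expect_equal(fine@gridSpacing, ffd@gridSpacing / 2)
  set.seed(34)
  pts <- matrix(runif(1500, 0, 47), 500, 3)
  expect_lt(max(abs(ffdDisplacement(ffd, pts) -
                    ffdDisplacement(fine, pts))), 1e-6)
})

test_that("transform serialization round-trips exactly", {
  aff <- affineTransform(matrix(c(1, .1, 0, -.1, 1, 0, 0, 0, 1.2), 3),
                         c(4, -2, 0.5), c(10, 10, 10))
  dom <- Volume(array(0, c(32, 32, 32)))
  ffd <- makeRandomFFD(dom, 8, 3, seed = 35)
  comp <- compositeTransform(aff, ffd)
  for (tr in list(aff, ffd, comp)) {
    f <- tempfile(fileext = ".txt")
    writeTransform(tr, f)
    back <- readTransform(f)
    expect_identical(class(tr), class(back))
    p <- matrix(runif(30, 5, 25), 10, 3)
    expect_equal(transformPoints(back, p), transformPoints(tr, p),
                 tolerance = 1e-12)
  }
})

test_that("mutual information matches direct evaluation on a tiny example", {
  # 4x4x4 volumes with small integer intensities, 2 bins, full grid:
  # MI must equal the hand-evaluated double sum to 1e-12
  set.seed(36)
  f <- array(sample(0:3, 64, TRUE), c(4, 4, 4))
  m <- array(sample(0:3, 64, TRUE), c(4, 4, 4))
  vf <- Volume(f); vm <- Volume(m)
  s <- miSettings(bins = 2, nSamples = 64, sampler = "grid")
  got <- mutualInformation(vf, vm, NULL, s)
  # independent oracle: explicit contingency table and double loop
  fb <- ifelse(as.vector(f) < 1.5, 1, 2)   # 2 equal-width bins over 0..3
  mb <- ifelse(as.vector(m) < 1.5, 1, 2)
  tab <- table(factor(fb, 1:2), factor(mb, 1:2)) / 64
  expected <- 0
  for (i in 1:2) for (j in 1:2) if (tab[i, j] > 0)
    expected <- expected + tab[i, j] *
      log2(tab[i, j] / (sum(tab[i, ]) * sum(tab[, j])))
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("MI equals the marginal entropy for identical images", {
  ph <- makeHeartPhantom(c(32, 32, 32), noiseSd = 2, seed = 37)
  v <- ph$volume
  s <- miSettings(bins = 32, nSamples = prod(dim(v)), sampler = "grid")
  mi <- mutualInformation(v, v, NULL, s)
  b <- volreg:::.hardBin(as.vector(v@voxels), range(v@voxels), 32)
  p <- tabulate(b + 1L, 32) / length(b); p <- p[p > 0]
  expect_equal(mi, -sum(p * log2(p)), tolerance = 1e-12)
})

test_that("MI is symmetric and vanishes for constant images", {
  a <- makeHeartPhantom(c(32, 32, 32), noiseSd = 2, seed = 38)$volume
  b <- makeHeartPhantom(c(32, 32, 32), noiseSd = 3, seed = 39)$volume
  s <- miSettings(bins = 16, nSamples = prod(dim(a)), sampler = "grid")
  expect_equal(mutualInformation(a, b, NULL, s),
               mutualInformation(b, a, NULL, s), tolerance = 1e-12)
  c1 <- Volume(array(1, c(16, 16, 16)))
  c2 <- Volume(array(5, c(16, 16, 16)))
  s2 <- miSettings(bins = 2, nSamples = prod(dim(c1)), sampler = "grid")
  expect_equal(mutualInformation(c1, c2, NULL, s2), 0)
})

test_that("MI peaks at the generating transform", {
  rc <- smallCase(seed = 40, maxDisp = 4, noiseSd = 1)
  s <- miSettings(bins = 32, nSamples = 8000, sampler = "grid")
  miTrue <- mutualInformation(rc$fixed, rc$moving, rc$trueTransform, s)
  miId <- mutualInformation(rc$fixed, rc$moving, NULL, s)
  expect_gt(miTrue, miId)
})

test_that("corresponding-point penalty arithmetic", {
  pairs <- data.frame(xF = c(0, 0), yF = c(0, 0), zF = c(0, 0),
                      xM = c(3, 0), yM = c(4, 2), zM = c(0, 0))
  expect_equal(cpPenalty(pairs[1, ], NULL), 5)      # 3-4-5 triangle
  pairs2 <- data.frame(xF = c(0, 0), yF = 0, zF = 0,
                       xM = c(2, 4), yM = 0, zM = 0)
  expect_equal(cpPenalty(pairs2, NULL), 3)          # mean of 2 and 4
  expect_error(cpPenalty(pairs[0, ], NULL), "pair")
  # permutation invariance and exact-alignment zero
  dom <- Volume(array(0, c(32, 32, 32)))
  ffd <- makeRandomFFD(dom, 8, 3, seed = 41)
  xF <- matrix(runif(60, 5, 25), 20, 3)
  xM <- transformPoints(ffd, xF)
  p <- data.frame(xF = xF[, 1], yF = xF[, 2], zF = xF[, 3],
                  xM = xM[, 1], yM = xM[, 2], zM = xM[, 3])
  expect_equal(cpPenalty(p, ffd), 0, tolerance = 1e-12)
  perm <- sample(20)
  expect_equal(cpPenalty(p, NULL), cpPenalty(p[perm, ], NULL),
               tolerance = 1e-12)
})

test_that("energy weight conventions and aligned-pair stationarity", {
  rc <- smallCase(seed = 42, maxDisp = 3, noiseSd = 1)
  ffd <- ffdGrid(rc$fixed, 16)
  tr <- compositeTransform(affineTransform(), ffd)
  s <- miSettings(bins = 16, nSamples = 2000, sampler = "grid")
  pts <- volreg:::.drawSamples(rc$fixed, s)
  e0 <- energyAndGradient(rc$fixed, rc$moving, rc$pairs, tr, omega = 0,
                          settings = s, samplePoints = pts)
  expect_equal(e0$E, -e0$mi, tolerance = 1e-12)
  # perfectly aligned pairs contribute nothing to the gradient
  xF <- matrix(runif(30, 8, 40), 10, 3)
  aligned <- data.frame(xF = xF[, 1], yF = xF[, 2], zF = xF[, 3],
                        xM = xF[, 1], yM = xF[, 2], zM = xF[, 3])
  eA <- energyAndGradient(rc$fixed, rc$moving, aligned, tr, omega = 0.5,
                          settings = s, samplePoints = pts)
  expect_equal(eA$gradient, e0$gradient, tolerance = 1e-12)
  expect_equal(eA$cp, 0, tolerance = 1e-12)
})

test_that("analytic energy gradient matches finite differences", {
  rc <- smallCase(seed = 43, maxDisp = 4, noiseSd = 2)
  ffd <- ffdGrid(rc$fixed, 16)
  set.seed(44)
  ffd@coefficients <- matrix(runif(nrow(ffd@coefficients) * 3, -2, 2),
                             ncol = 3)
  tr <- compositeTransform(affineTransform(), ffd)
  s <- miSettings(bins = 32, nSamples = 4000, sampler = "grid")
  pts <- volreg:::.drawSamples(rc$fixed, s)
  an <- energyAndGradient(rc$fixed, rc$moving, rc$pairs, tr, 0.01, s,
                          samplePoints = pts)
  eps <- 1e-5
  Efun <- function(co) {
    f2 <- ffd; f2@coefficients <- co
    energyAndGradient(rc$fixed, rc$moving, rc$pairs,
                      compositeTransform(affineTransform(), f2), 0.01, s,
                      samplePoints = pts)$E
  }
  idx <- which(abs(an$gradient) > 1e-5, arr.ind = TRUE)
  set.seed(45)
  sel <- idx[sample(nrow(idx), 12), , drop = FALSE]
  for (r in seq_len(nrow(sel))) {
    co <- ffd@coefficients
    cp <- co; cp[sel[r, 1], sel[r, 2]] <- cp[sel[r, 1], sel[r, 2]] + eps
    cm <- co; cm[sel[r, 1], sel[r, 2]] <- cm[sel[r, 1], sel[r, 2]] - eps
    fd <- (Efun(cp) - Efun(cm)) / (2 * eps)
    expect_equal(an$gradient[sel[r, 1], sel[r, 2]], fd,
                 tolerance = 1e-4)
  }
})
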