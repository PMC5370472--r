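test_that("descriptor shape, normalization and degenerate patches", {
  set.seed(21)
  n <- 40
  v <- Volume(array(rnorm(n^3), c(n, n, n)))
  kp <- data.frame(x = 20, y = 20, z = 20, ix = 20, iy = 20, iz = 20,
                   scale = 2, response = 1, detector = "dog")
  fd <- computeDescriptors(v, kp)
  expect_identical(dim(fd$vectors), c(1L, 4096L))
  expect_true(all(fd$vectors >= 0))
  expect_equal(sqrt(sum(fd$vectors^2)), 1, tolerance = 1e-9)
  # constant patch -> all-zero sentinel
  flat <- Volume(array(1, c(n, n, n)))
  fd0 <- computeDescriptors(flat, kp)
  expect_true(all(fd0$vectors == 0))
  # border handling
  edge <- data.frame(x = 2, y = 2, z = 2, ix = 2, iy = 2, iz = 2,
                     scale = 2, response = 1, detector = "dog")
  expect_identical(nrow(computeDescriptors(v, edge)$keypoints), 0L)
  expect_error(computeDescriptors(v, edge, skipBorder = FALSE), "window")
})

test_that("a pure +x gradient occupies a single azimuth bin column", {
  n <- 40
  ramp <- Volume(array(rep(seq(0, 1, length.out = n), n * n), c(n, n, n)))
  kp <- data.frame(x = 20, y = 20, z = 20, ix = 20, iy = 20, iz = 20,
                   scale = 2, response = 1, detector = "dog")
  vec <- computeDescriptors(ramp, kp)$vectors[1, ]
  # bin layout: index = 1 + elevation + 8*azimuth + 64*subregion
  azOf <- rep(rep(0:7, each = 8), 64)
  elOf <- rep(0:7, 8 * 64)
  expect_equal(sum(vec[azOf != 0]), 0, tolerance = 1e-12)
  # gradient lies in the xy-plane: mass splits between the two
  # equatorial elevation bins only
  expect_equal(sum(vec[!(elOf %in% c(3, 4))]), 0, tolerance = 1e-12)
})

test_that("descriptors are exactly reproducible", {
  set.seed(22)
  v <- Volume(array(rnorm(40^3), c(40, 40, 40)))
  kp <- data.frame(x = 0, y = 0, z = 0, ix = c(18, 22), iy = c(20, 19),
                   iz = c(20, 21), scale = 2, response = 1, detector = "dog")
  a <- computeDescriptors(v, kp)$vectors
  b <- computeDescriptors(v, kp)$vectors
  expect_identical(a, b)
})

test_that("ratio-test matching equals an exhaustive evaluation on planted sets", {
  set.seed(23)
  mkFeat <- function(m) {
    m <- volreg:::.normalizeDescriptors(m)
    list(keypoints = data.frame(x = seq_len(nrow(m)), y = 0, z = 0),
         vectors = m)
  }
  F <- mkFeat(matrix(runif(10 * 4096), 10))
  M <- mkFeat(matrix(runif(14 * 4096), 14))
  t4 <- 0.995   # uniform random vectors have ratios near 1
  got <- matchFeatures(F, M, t4)
  # brute-force oracle: all-pairs distances, ratio test, one-to-one
  d <- as.matrix(stats::dist(rbind(F$vectors, M$vectors)))[1:10, 11:24]
  cand <- data.frame()
  for (u in 1:10) {
    o <- order(d[u, ])
    r <- d[u, o[1]] / d[u, o[2]]
    if (r < t4) cand <- rbind(cand, data.frame(u = u, v = o[1], r = r))
  }
  keep <- do.call(rbind, lapply(split(cand, cand$v), function(g)
    g[order(g$r, g$u)[1], ]))
  keep <- keep[order(keep$u), ]
  expect_identical(nrow(got), nrow(keep))
  expect_equal(got$xF, keep$u, ignore_attr = TRUE)
  expect_equal(got$xM, keep$v, ignore_attr = TRUE)
  expect_equal(got$ratio, keep$r, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("degenerate matching cases follow the documented conventions", {
  base <- matrix(runif(3 * 4096, 0.1, 1), 3)
  feats <- function(m) list(keypoints = data.frame(x = seq_len(nrow(m)),
                                                   y = 0, z = 0),
                            vectors = volreg:::.normalizeDescriptors(m))
  F <- feats(base)
  # identical copy with distinct descriptors: every feature self-matches
  got <- matchFeatures(F, F, 0.9)
  expect_identical(nrow(got), 3L)
  expect_true(all(got$ratio == 0))
  expect_equal(got$xF, got$xM)
  # two identical moving descriptors (ratio exactly 1) are rejected
  M2 <- feats(base[c(1, 1, 2), ])
  got2 <- matchFeatures(feats(base[1, , drop = FALSE]), M2, 0.9)
  expect_identical(nrow(got2), 0L)
  # single moving feature: accepted only on exact match
  M1 <- feats(base[1, , drop = FALSE])
  expect_identical(nrow(matchFeatures(feats(base[2, , drop = FALSE]),
                                      M1, 0.9)), 0L)
  self1 <- matchFeatures(M1, M1, 0.9)
  expect_identical(nrow(self1), 1L)
  expect_identical(self1$ratio, 0)
})

test_that("matching is monotone in t4 and stable to input order", {
  set.seed(24)
  feats <- function(m) list(keypoints = data.frame(x = seq_len(nrow(m)),
                                                   y = 0, z = 0),
                            vectors = volreg:::.normalizeDescriptors(m))
  F <- feats(matrix(runif(8 * 4096), 8))
  M <- feats(matrix(runif(12 * 4096), 12))
  n99 <- nrow(matchFeatures(F, M, 0.999))
  n90 <- nrow(matchFeatures(F, M, 0.99))
  expect_lte(n90, n99)
  # permuting the moving list leaves the matched positions unchanged
  perm <- sample(12)
  Mp <- list(keypoints = M$keypoints[perm, , drop = FALSE],
             vectors = M$vectors[perm, , drop = FALSE])
  a <- matchFeatures(F, M, 0.999)
  b <- matchFeatures(F, Mp, 0.999)
  expect_equal(a[order(a$xF), c("xF", "xM", "ratio")],
               b[order(b$xF), c("xF", "xM", "ratio")], ignore_attr = TRUE)
})

test_that("end-to-end matching recovers an integer translation", {
  ph <- makeHeartPhantom(c(48, 48, 48), noiseSd = 1, seed = 25)
  v <- ph$volume
  t <- c(3, 0, -2)
  mov <- resample(v, affineTransform(translation = t))  # mov(x) = v(x + t)
  kF <- detectKeypoints(mov, harrisParams(sigmaIList = 1.4^(0:4)),
                        dogParams())
  kM <- detectKeypoints(v, harrisParams(sigmaIList = 1.4^(0:4)),
                        dogParams())
  fF <- computeDescriptors(mov, kF)
  fM <- computeDescriptors(v, kM)
  pairs <- matchFeatures(fF, fM, 0.9)
  expect_gt(nrow(pairs), 5)
  # fixed = translated copy, so the true map is xM = xF + t
  err <- sqrt((pairs$xM - pairs$xF - t[1])^2 +
              (pairs$yM - pairs$yF - t[2])^2 +
              (pairs$zM - pairs$zF - t[3])^2)
  expect_gte(mean(err <= 2), 0.9)
})
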