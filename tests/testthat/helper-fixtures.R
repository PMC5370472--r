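# Fixture builders shared across the suite. Everything is generated in
# code under fixed seeds; no data files.

# bright cube on dark background; corners at 0-based index lo and hi
cubeVolume <- function(n = 48, lo = 17, hi = 32) {
  arr <- array(0, c(n, n, n))
  arr[lo:hi, lo:hi, lo:hi] <- 1
  list(vol = Volume(arr), corners = as.matrix(expand.grid(
    c(lo - 1, hi - 1), c(lo - 1, hi - 1), c(lo - 1, hi - 1))))
}

# isotropic Gaussian blob of scale sigma centred at ctr (1-based index)
blobVolume <- function(n = 48, sigma = 3, ctr = c(24, 24, 24)) {
  ix <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  r2 <- rowSums(sweep(ix, 2, ctr)^2)
  Volume(array(exp(-r2 / (2 * sigma^2)), c(n, n, n)))
}

randomVolume <- function(n = 8, seed = 1, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0)) {
  set.seed(seed)
  Volume(array(rnorm(prod(rep(n, 3))), rep(n, 3)), spacing, origin)
}

# small deterministic registration case reused by several tests
smallCase <- function(seed = 7, n = 48, warpSpacing = 16, maxDisp = 4,
                      noiseSd = 2) {
  makeRegistrationCase(rep(n, 3), c(1, 1, 1), warpSpacing = warpSpacing,
                       maxDisp = maxDisp, noiseSd = noiseSd, seed = seed)
}

# independent loop-based Gaussian-derivative convolution used as the
# brute-force oracle for the Harris response (reflective borders,
# matching the package's stated kernel definitions but evaluated point
# by point with explicit loops)
oracleConvAt <- function(arr, kx, ky, kz, at) {
  d <- dim(arr)
  refl <- function(i, n) {
    if (n == 1) return(1L)
    p <- 2L * n
    i <- ((i - 1L) %% p + p) %% p
    if (i < n) i + 1L else p - i
  }
  rx <- (length(kx) - 1L) / 2L
  ry <- (length(ky) - 1L) / 2L
  rz <- (length(kz) - 1L) / 2L
  acc <- 0
  for (a in -rx:rx) for (b in -ry:ry) for (c in -rz:rz) {
    acc <- acc + kx[a + rx + 1] * ky[b + ry + 1] * kz[c + rz + 1] *
      arr[refl(at[1] + a, d[1]), refl(at[2] + b, d[2]), refl(at[3] + c, d[3])]
  }
  acc
}

# desk-scale registration configuration used across the regression tests
deskSched <- function() multiresSchedule(c(2, 1), c(16, 8))
deskOpt <- function(seed, iterations = 300, a = 2000)
  asgdSettings(a = a, iterations = iterations, seed = seed)
deskAffineOpt <- function(seed) asgdSettings(a = 400, iterations = 300,
                                             seed = seed)
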