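---
title: "Feature-constrained B-spline registration and atlas-based segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-constrained B-spline registration and atlas-based segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Atlas-based segmentation transfers an expert labelling from a reference
(atlas) image to a new, unsegmented image by recovering the spatial
transform that aligns the two and carrying the labels through it. For
cardiac CT the six substructures of interest (aorta, left/right atria,
left/right ventricular blood pools, left-ventricular myocardium) show
large inter-subject shape variation and locally ambiguous boundaries, so
a purely intensity-driven nonrigid registration can drift precisely where
the anatomy is hardest. `volreg` implements a registration that
counteracts this by blending two information sources:

* **Mutual information (MI).** With `f` the fixed-image and `m` the
  moving-image intensity, MI is estimated from the joint histogram of
  `(f(x), m(T(x)))` over sampled points `x`:
  `MI = sum_{f,m} p(f,m) log2( p(f,m) / (pF(f) pM(m)) )`,
  marginals by summation over the joint.
* **Corresponding-point penalty (CP).** Feature points are detected in
  both images, described, and matched; the penalty is the mean residual
  `C_p = (1/P) sum_i || xM_i - T(xF_i) ||` in mm.

The registration minimizes

```
E(mu) = -MI(mu) + omega * C_p(mu),        omega = 0.01 by default
```

over the parameters `mu` of a cubic B-spline free-form deformation (FFD),
after an affine pre-alignment. The sign convention makes `E` a descent
target: better intensity agreement and tighter landmark residuals both
lower the energy. The combined transform is additive in displacement,
`T(x) = affine(x) + u_FFD(x)`, with the affine solved first and frozen.

Feature pairs come from two detectors whose outputs are concatenated:

* a **scale-adapted multi-scale Harris** corner detector — the response is
  `det(H) - alpha * trace(H)^3` of the smoothed gradient outer-product
  matrix `H = sigmaD^2 g(sigmaI) * [grad I grad I^T]`, with the
  characteristic scale picked where the Laplacian-of-Gaussian operator
  `sigma^2 |L_xx + L_yy|` peaks across the scale list; and
* a **difference-of-Gaussians (DoG)** scale-space extrema detector over a
  downsampled pyramid, keeping voxels that are strict extrema over the 26
  spatial neighbours plus the two 27-voxel blocks in the adjacent scales.

Each keypoint receives a 4096-dimensional volumetric SIFT-style
descriptor (4×4×4 spatial subregions × 8 azimuth × 8 elevation
gradient-orientation bins, trilinear/bilinear soft-binning, Gaussian
spatial weighting, unit normalization with a 0.2 clamp). Matching is
exact nearest-neighbour in descriptor space with the ratio test
`d(u,v)/d(u,v') < T4`, made one-to-one by keeping the lowest-ratio match
per moving feature.

## Parameters and their defaults

| Parameter | Default | Meaning |
|---|---|---|
| `sigmaIList` | `1.5 * 2^(0:4)` voxels | Harris integration scales |
| `sigmaDRatio` | 0.7 | differentiation scale / integration scale |
| `alpha` | 0.006 | trace weight in the corner response (see below) |
| `t1` | 0.1 | corner threshold, as a fraction of the peak response |
| `t2` | 0.1 | LoG scale-selection threshold (normalized intensities) |
| `blurSigma`, `scaleFactor` | 1.5 voxels, 2 | DoG pyramid construction |
| `t3` | 0.0075 | DoG extremum magnitude threshold |
| `t4` | 0.9 | descriptor ratio-test threshold |
| `omega` | 0.01 | CP weight, with `C_p` in mm |
| `bins`, `nSamples` | 32, 2048 | MI histogram and sampling |
| `A`, `tau`, `a`, iterations | 50, 0.602, 2000, 1000 | optimizer gain law |
| smoothing / grid schedule | 8,4,2,1 voxels; 80,40,20,10 mm | four levels |

Two defaults deserve explanation because the conventional constants do
not transfer to 3D unchanged:

* **`alpha = 0.006`.** The classic 2D corner response uses
  `det - 0.04 trace^2`. With the cubed trace of the 3D form, AM–GM gives
  `det(H) <= trace(H)^3 / 27` for any positive-semidefinite `H`, so any
  `alpha >= 1/27 ≈ 0.037` makes the response non-positive everywhere and
  no corner can pass a positive threshold. The default 0.006 reproduces
  the 2D margin (`1 - 4*0.04 = 0.84 = 1 - 27*0.006`); `alpha` remains a
  parameter.
* **`t1` as a relative threshold.** The corner response scales with the
  6th power of the intensity range. Volumes are min–max normalized to
  [0, 1] before detection so that `t2`/`t3` are meaningful across inputs,
  and on that scale an absolute corner cut of 0.1 would never fire; `t1`
  therefore thresholds at `t1 * max(response)`, which is invariant to
  intensity scaling and keeps 0.1 as a sensible default.

## Optimizer and multiresolution scheme

The energy is minimized by stochastic gradient descent with the
deterministic decaying gain `gamma(k) = a / (A + k + 1)^tau`; the
stochasticity lives in the MI sampling, which re-draws its `nSamples`
points every iteration from a seeded stream, so runs are exactly
reproducible. The MI gradient is analytic: the joint histogram uses hard
binning on the fixed axis and a cubic B-spline Parzen window on the
moving axis, making MI differentiable in `mu`; the CP gradient follows
the unit residual vectors through the B-spline weights (pairs within
1e-9 mm contribute zero — the subgradient choice at the kink). A
finite-difference fallback (`miGradient = "fd"`) exists for validation.

Coarse-to-fine proceeds by smoothing the *moving* image with the level's
Gaussian (no downsampling), and by refining the control lattice with the
exact dyadic cubic B-spline subdivision rules
(`c'_{2i} = (c_{i-1} + 6 c_i + c_{i+1})/8`, `c'_{2i+1} = (c_i + c_{i+1})/2`),
which reproduces the coarse displacement field to machine precision
before further optimization; schedules must therefore halve their grid
spacing between levels. Landmarks are detected once at full resolution
and reused at every level, keeping `P` and hence the meaning of `omega`
constant.

Affine pre-registration optimizes the 12 parameters with the same
optimizer; matrix entries are rescaled by the domain radius so matrix and
translation steps are commensurate, and the returned parameters average
the final quarter of the iterates, which suppresses the stationary
random walk the stochastic MI gradient induces at non-vanishing gain.

## The synthetic phantom and what it does (not) show

Because the framework is validated without patient data, the package
ships a first-class generator:

* `makeHeartPhantom()` builds six pairwise-disjoint structures (an aortic
  tube, two atria, two ventricular pools and a *closed* myocardial shell
  around the LV) with distinct mean intensities on a 0–100 scale,
  slightly blurred interfaces, and additive Gaussian noise.
* `makeRandomFFD()` draws i.i.d. uniform control-point displacements in
  `[-maxDisp, maxDisp]` (boundary ring frozen at zero), giving a smooth
  ground-truth warp that is bounded by `maxDisp` through the partition of
  unity.
* `makeRegistrationCase()` composes the two: the phantom is the moving
  image, the fixed image is the phantom resampled through the true warp
  (so `resample(moving, T_true) == fixed` exactly before noise), both
  get independent noise, and landmark pairs are sampled on structure
  boundaries — mirroring where real detectors fire — with
  `xM = T_true(xF) + N(0, landmarkNoise)`.

The study conditions used throughout the regression suite and the
acceptance script are 64³ voxels at 1 mm, warp spacing 16 mm, maximum
displacement 6 mm, intensity noise 2% of the range, 40 landmarks with
0.5 mm jitter — a desk-scale analogue of clinical volumes chosen so ten
full registrations run in minutes on one CPU. Desk-scale runs use a
two-level schedule (smoothing 2, 1 voxels; grids 16, 8 mm), 300
iterations per level, and an affine gain `a = 400`; the paper-scale
defaults remain on the constructors.

The phantom drives MI (distinct per-structure intensities), both
detectors (corners and blobs at structure boundaries) and the evaluation
metrics, and its ground truth makes landmark error exactly measurable.
It does **not** emulate CT physics (beam hardening, motion artifacts),
textured tissue, or population shape variability; a passing suite
demonstrates the correctness and the qualitative behaviour of the
machinery — feature constraints improving boundary alignment — not
clinical accuracy levels.

## Numerical choices and degenerate inputs

* Geometry is axis-aligned; indices are 0-based; all landmark and
  transform arithmetic is in world mm. Files with non-identity direction
  matrices are rejected.
* Smoothing uses half-sample symmetric (reflective) borders, which makes
  the convolution operator doubly stochastic and preserves the mean
  intensity exactly.
* Resampling outside the moving domain yields 0 (air after
  normalization); out-of-domain MI samples are dropped, with a warning
  past 50%.
* The FFD clamps its grid coordinate at the lattice margin (displacement
  continues constant); the Jacobian refuses out-of-domain points.
* Parzen binning maps the moving intensity range onto the interior bin
  span `[1, bins-2]` so the cubic support never leaves the histogram and
  the gradient needs no boundary cases.
* Strict inequalities everywhere in extrema detection: plateaus are never
  keypoints (deterministic and conservative).
* Matching ties break to the lower index; with a single moving feature a
  ratio is undefined and only an exact match (distance 0) is accepted.
* Dice of a label empty in both maps is 1 with a warning; surface
  distances refuse empty labels; the signed-rank test is exact for
  n ≤ 25 untied pairs and a corrected normal approximation otherwise.
* Surface distance is one-directional (seg → gold) by default, matching
  the reported convention; a symmetric option exists. The whole-heart
  summary reports both the mean-of-means and the pooled-over-points
  convention, since either may be wanted.

## Known limitations

* Eq.-level LoG scale selection uses the two-term `|L_xx + L_yy|`
  operator by default (`logIncludeZz` adds the axial term); on strongly
  anisotropic structures the two variants select different scales.
* No orientation assignment: descriptors are translation- but not
  rotation-invariant, which suffices for the small-rotation cardiac
  setting the framework targets.
* No folding penalty or diffeomorphism guarantee on the FFD; the
  ground-truth warps used for validation stay within the invertible
  regime (`maxDisp < 0.4 *` warp spacing).
* Atlas construction averages intensity images after registration to the
  reference; no statistical shape modelling or multi-atlas fusion.
* Time phases are treated as independent 3D problems; there is no 4D
  temporal regularization.
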