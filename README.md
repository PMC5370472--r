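# volreg

Feature-constrained nonrigid registration and atlas-based segmentation of
3D volumes, written for the cardiac-CT setting: six substructures (AO,
LA, LV, LVM, RA, RV) are transferred from a labelled atlas to an
unsegmented image by recovering the deformation that aligns the two.

Intensity-only registration drifts where cardiac boundaries are ambiguous
(most notoriously the left-ventricular myocardium). `volreg` counteracts
this by adding automatically matched feature points as a penalty inside
the registration energy

    E(mu) = -MI(mu) + omega * C_p(mu)

where `MI` is the mutual information between the fixed image `f` and the
warped moving image `m(T_mu(x))`, estimated from a joint intensity
histogram, and

    C_p = (1/P) * sum_i || xM_i - T_mu(xF_i) ||     (mm)

is the mean residual of `P` corresponding points found by 3D keypoint
detection (multi-scale Harris corners + difference-of-Gaussians extrema),
4096-dimensional volumetric SIFT-style description, and nearest-neighbour
matching under the ratio test `d(u,v)/d(u,v') < T4`. `T_mu` is an affine
pre-alignment plus a cubic B-spline free-form deformation optimized
coarse-to-fine by stochastic gradient descent with decaying gain
`a/(A+k+1)^tau`. Segmentations are propagated by nearest-neighbour
resampling of the atlas labels through the recovered transform and scored
with Dice overlap, mm surface distances, paired Wilcoxon tests and
Cohen's d.

Because no patient data ships with the package, a first-class phantom
module generates six-substructure cardiac-like volumes, ground-truth
B-spline warps and boundary landmark pairs, so every stage is validated
against known answers.

## Worked example

```r
library(volreg)

# a synthetic case: fixed = phantom warped by a known 16 mm-spacing FFD
# (max displacement 6 mm) + 2% noise; moving = the original phantom
rc <- makeRegistrationCase(c(64, 64, 64), warpSpacing = 16, maxDisp = 6,
                           noiseSd = 2, seed = 3)

sched <- multiresSchedule(c(2, 1), c(16, 8))   # desk-scale schedule
mis   <- miSettings(nSamples = 2048)

aff <- registerAffine(rc$fixed, rc$moving, mis,
                      asgdSettings(a = 400, iterations = 300, seed = 5))
tr  <- registerMICP(rc$fixed, rc$moving, rc$pairs, omega = 0.01,
                    sched, mis,
                    asgdSettings(iterations = 300, seed = 7), initial = aff)

seg <- propagateLabels(atlas(rc$moving, rc$movingLabels), tr, rc$fixed)

xF <- as.matrix(rc$pairs[, 1:3])
xT <- transformPoints(rc$trueTransform, xF)
round(c(affine = mean(sqrt(rowSums((transformPoints(aff, xF) - xT)^2))),
        mi_cp  = mean(sqrt(rowSums((transformPoints(tr, xF) - xT)^2)))), 3)
#> affine  mi_cp
#>  1.007  0.387
round(c(LV  = diceCoefficient(seg, rc$fixedLabels, 3),
        LVM = diceCoefficient(seg, rc$fixedLabels, 4)), 4)
#>     LV    LVM
#> 0.9694 0.9260
```

The first pair of numbers is the mean ground-truth landmark error in mm:
the feature-constrained B-spline registration reduces the residual left
by the affine stage by roughly a factor of three. The Dice scores
measure the overlap of the propagated labels with the ground-truth
segmentation of the fixed image; the myocardial shell (LVM), the hardest
structure, is where the corresponding-point penalty helps most — with
`omega = 0` (pure MI) the same case scores 0.9155.

A thin command-line front end over the same functions is installed at
`inst/cli/volreg.R` (subcommands `phantom`, `detect`, `match`,
`register`, `segment`, `evaluate`).

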