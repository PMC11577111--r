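---
title: "Whole-body atlas construction with bodyatlas: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body atlas construction with bodyatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`bodyatlas` builds population-averaged whole-body MRI atlases.  The pipeline
partitions a cohort into six sex-by-BMI groups, selects a median-phenotype
reference subject per group, registers every subject to that reference
(affine, then diffeomorphic B-spline free-form deformation), averages the
registered images and one-hot-encoded label maps into anatomical and
probabilistic label atlases, and removes the reference bias by warping the
initial atlas with the average of the inverted subject deformations.
A voxel-based morphometry (VBM) module compares atlas-space tissue maps
between groups with a per-voxel general linear model under
false-discovery-rate control.

Because real whole-body cohorts are access-restricted, the package ships a
first-class phantom module: synthetic 3D bodies with seven labelled
structures and *known* ground-truth deformations, so every stage can be
validated against simulated truth rather than surrogates alone.

# Data model and conventions

All spatial objects are S4 classes on axis-aligned regular grids:
`BodyVolume` (scalars), `LabelVolume` (integer ids plus a dictionary),
`DisplacementField` (3-component mm vectors), `AffineTransform3D`
(`y = Lx + t`, physical mm) and `VelocityLattice` (cubic B-spline
coefficients of a stationary velocity field).  The physical position of
voxel `(i, j, k)` (1-based) is `origin + (c(i, j, k) - 1) * spacing`.

One warping convention is used throughout: **pull-back**.  A field `u` on
the fixed grid maps fixed points `x` to moving points `x + u(x)`;
`warpVolume()` resamples the moving image at those points, so every output
lives on the fixed grid.  This is the convention under which averaging
warped images (`A_init = (1/n) sum I_i o phi_i`) is well defined.
Composition follows the same algebra:
`composeFields(outer, inner)(x) = inner(x) + outer(x + inner(x))`, i.e.
warping by the result equals warping by `outer` and then by `inner`.
Out-of-domain *intensity* samples read as 0 (background); out-of-domain
*vector* samples are edge-clamped, which keeps the fixed-point inversion and
scaling-and-squaring stable near the boundary.

# Registration

## Objective

Pairwise registration minimises

```
metric(F, M o phi)  +  lambda * bendingEnergy(v)
```

where `phi` is, in sequence: a centre-of-mass (or trimmed-ICP rigid)
initialisation, a 12-dof affine (translation, rotation, log-scale, shear,
optimised by BFGS with analytic chain-rule gradients over a factor-2 image
pyramid), and the unit-time flow of a stationary velocity field `v`
parameterised on a cubic B-spline control-point lattice.  The flow is
computed by scaling and squaring (`integrateVelocity()`, 6 steps by
default); velocities are capped so the scaled integration step stays below
0.4 voxel, a sufficient condition for a positive Jacobian, hence the
transform is diffeomorphic by construction and the folding ratio of every
deformable output is logged.

The default metric is `ncc` (1 minus global normalised cross-correlation),
appropriate for same-modality phantom and water-contrast images and
invariant to affine intensity changes; `ssd` and a 64-bin `nmi` are
available for other settings.

## Regularisation and its units

`bendingEnergy()` is the standard free-form-deformation thin-plate penalty:
the mean over voxels of the squared second spatial derivatives of the dense
velocity (mixed terms twice).  Because the 3D B-spline basis is a tensor
product, the voxel sum factorises into per-axis Gram matrices, so the
penalty and its gradient are computed exactly without materialising dense
derivative fields.

Derivatives are taken, by default, with respect to the dimensionless
control-point coordinate (`units = "cp"`), following the convention of the
reference FFD implementations; physical-mm derivatives are available
(`units = "mm"`).  The difference matters: on a typical whole-body grid the
mm-unit energy of a realistic field is of order 1e-5, so any small `lambda`
would leave the deformation effectively unregularised and the optimiser
free to chase interpolated noise.  In control-point units the energy is
O(0.1) and the default `lambda = 1e-3` behaves as intended.  We calibrated
this once on a single planted-deformation phantom pair: with `lambda =
1e-3` the recovered field's mean interior endpoint error is about one third
of a voxel, with organ Dice 0.95 and folding ratio 0; with mm units the
same run overfits (endpoint error about 2 voxels despite *better* metric
values than the ground truth).

## Multi-resolution schedule

Three pyramid levels by factor-2 anti-aliased downsampling (Gaussian
prefilter, sigma `0.5*sqrt(factor^2-1)` voxels), control-point spacing
32/16/8 mm coarse to fine.  Both fixed and moving images are downsampled
through the same pyramid — warping the full-resolution moving image onto a
coarse grid without prefiltering would alias, and the optimiser would chase
the aliasing difference.  Each level's total transform initialises the next
(`total = init o exp(v)`, composed on the finer grid).  Within a level the
lattice coefficients follow the image-force direction (the metric's
intensity gradient times the warped image gradient, projected onto the
B-spline basis — the one-step approximation of the gradient through the
scaling-and-squaring recursion), with a backtracking line search on the
*exact* objective, so accepted steps never increase it; optimisation stops
at a relative objective change of 1e-5 or 100 iterations.

# Atlas construction and unbiasing

`buildInitialAtlas()` averages the subjects warped into reference space and
exports a coverage map (fraction of subjects sampled in-domain per voxel);
`buildLabelAtlas()` one-hot encodes each structure, warps with *linear*
interpolation and averages, yielding smooth probability maps.
`averageInverseField()` inverts each subject field by fixed-point iteration
(`u_inv <- -u(x + u_inv)`, tolerance 0.01 mm, 50 iterations, residuals
reported; non-convergence aborts with the subject identified) and averages
the inverses; `unbiasAtlas()` warps the anatomical *and* every probability
volume by the average inverse field.  The inversion operates on the total
(affine-composed) field: averaging inverses is meaningful only if each
field carries the full reference-to-subject map.  For a population of pure
translations the unbiased atlas equals the initial atlas shifted by the
negated mean translation exactly, which the test suite asserts; for a
population symmetric about the template with a deliberately off-centre
reference, unbiasing demonstrably moves the atlas centroid back toward the
population mean.

# Cohort handling

BMI is `weight / (height/100)^2`.  Categories are half-open — normal
`[18.5, 25)`, overweight `[25, 30)`, obese `[30, Inf)` — with 30 assigned
to obese (WHO convention) and 18.5 as the inclusion floor.  The healthy
filter keeps subjects with no cancer record, no self-reported disease and
no operation history; a missing flag is treated conservatively as unknown
and excluded, with one logged line per exclusion.

Reference selection must realise "the median subject" across five
phenotypes (age, weight, height, BMI, body-fat %), which no single subject
attains exactly; we therefore scale each component by its within-group MAD
(zero-spread components fall back to unscaled distance) and return the
subject closest to the component-wise median vector in that metric, with
ties broken deterministically by subject id.  The selected subject's
phenotypes are attached to the result so the choice can be reviewed — the
programmatic stand-in for a clinical expert's visual check.

# The phantom module

`makeTemplate()` paints an ellipsoidal body with a subcutaneous-fat shell,
random visceral-fat blobs and five organ ellipsoids (liver, spleen,
pancreas, two kidneys), each with a tissue mean intensity plus Gaussian
noise (water-contrast convention: organs and lean tissue bright, fat dark,
background exactly 0).  Defaults: 64 x 48 x 96 voxels at 3 mm — the
neck-to-knee aspect ratio at a reduced scale chosen so a full registration
runs in minutes on one CPU; organ volumes match their analytic ellipsoid
volumes to within discretisation error (about 2 percent).

`sampleSubject()` applies a ground-truth transform
`phi_true = affine(scale, translation) o exp(velocity)` with the velocity
drawn as white noise convolved with a Gaussian kernel (correlation length
24 mm), rescaled to a 6 mm peak amplitude, then integrated — smooth,
controllable and folding-free (checked; a folding draw is rejected with a
diagnostic).  Scale is drawn from [0.95, 1.05] and translation from
+-9 mm per axis.  Everything is reproducible from the seed, and zero
deformation reproduces the template bit for bit.

The disease effect for the VBM experiment is a *perirenal fat capsule*: a
contiguous visceral-fat layer around both kidneys whose thickness is drawn
per subject from a Gaussian (18 +- 2.5 mm); the diseased subgroup's mean
thickness is 1.3 times the healthy mean — a +30 percent regional fat
increase.  We model the effect as a coherent anatomical structure rather
than independent per-voxel fat noise: independent Bernoulli voxels would
put an sd of 0.5 at every voxel and make a 30 percent group difference
statistically invisible at realistic sample sizes, which is neither how
regional adiposity behaves nor a detectable planted effect.  The planted
region reported by `makeCohort()` is the set of voxels whose analytic
capsule-coverage probability differs between groups by more than 0.5.

What the phantoms do *not* emulate: Dixon water/fat separation, bias
fields, scan-station stitching seams, organ-specific motion, or
between-subject intensity variation beyond additive noise.  Passing tests
therefore validate the algorithms' correctness and the pipeline's
statistical behaviour under known truth — not performance on real scanner
data, whose registration difficulty is dominated by exactly those effects.

# Pre-processing

Intensity normalisation is min-max to [0, 1] with percentile-window
contrast enhancement (default window (1, 99), configurable); all intensity
statistics are computed inside the automatic body mask so background noise
cannot shift the scale.  The body mask uses a three-class Otsu threshold —
the *lowest* threshold separates the dark background from the fat and lean
tissue modes; a classic bimodal Otsu tends to split between fat and lean
and amputate the subcutaneous shell — followed by the largest 6-connected
component, a 3x3x3 morphological closing and interior hole filling.
Inputs with a large exactly-zero background (previously masked outputs,
noise-free phantoms) short-circuit the histogram threshold, and an input
already saturated at both window ends is passed through unchanged, which
makes the full pre-processing exactly idempotent.  Spatial initialisation
aligns mask centroids; `mode = "icp"` refines to a rigid transform on
subsampled mask-surface voxels (6-neighbour erosion difference) with
nearest-neighbour correspondences, a 10 percent trimmed Kabsch update and
at most 100 iterations, falling back to the centroid translation with a
warning if it does not converge.

# Voxel-based morphometry

Atlas-space maps are smoothed with a spacing-aware Gaussian (default FWHM
2 voxels; the kernel size is a free analysis choice, exposed in the
interface).  The per-voxel two-group GLM reduces to the pooled-variance
two-sample t-test; the two-sided p-value is mapped to a signed z-score
(positive where the pathological group mean exceeds the healthy mean).
Voxels with zero pooled variance carry no test: they are flagged, set to
z = 0 and excluded from the analysis mask, so they do not enter the
Benjamini-Hochberg correction (leaving them in would dilute the correction
by the empty background).  Significance requires surviving BH at level `q`
*and* a corrected p-value below the retention threshold (default 0.001).
Group sizes are balanced by seeded subsampling of the larger group.  The
default design has no covariates; age or BMI columns can be added to the
maps' group structure by the caller before testing.

Under the null the mean false-discovery proportion over 200 simulated
replicates stays below `q` within Monte-Carlo error (asserted in the test
suite).  In the planted-effect experiment (15 vs 15 subjects, +30 percent
capsule), the test suite normalises the fat maps with the phantoms'
ground-truth inverse fields rather than 30 fresh FFD registrations: the
statistical stage is what is under test there, registration recovery is
validated separately, and the substitution keeps the suite's runtime
within minutes.

# Numerical choices and degenerate inputs

* Field inversion: fixed-point iteration, tolerance 0.01 mm, 50 iterations
  default; non-convergence is an error (never a silent return).
* Jacobians: central differences scaled by spacing, one-sided at the
  boundary; folding statistics exclude the one-voxel boundary ring where
  one-sided stencils would bias the estimate.
* Interpolation: linear for intensities and probability maps, nearest for
  raw label ids.
* Dice of two empty masks is 1; empty-vs-non-empty is 0.  HD95 uses
  6-connectivity boundary voxels, an exact Euclidean distance transform,
  and the max-of-directed-95th-percentiles convention (quantile type 7).
* Constant volumes are rejected by the normalisers (undefined scale);
  empty masks and empty groups are errors naming the stage.
* Degenerate percentile windows (clipped range of width zero) are errors.

# Problem sizes used in the validation suite

Unit and property tests run on 8-16 voxel grids where oracles (brute-force
stencils, matrix exponentials, exhaustive pairwise distances) are exact and
fast.  End-to-end registration checks run at the phantom default
64 x 48 x 96 at 3 mm; the monotone-improvement suite and the VBM planted
experiment use 32 x 24 x 48 at 6 mm, sizes at which a complete run of the
suite takes a few minutes on a single core while exercising every stage of
the pipeline.

# Known limitations

* Intensity-driven registration cannot constrain deformation inside
  homogeneous tissue; interior accuracy beyond the regulariser's
  interpolation is only as good as the visible structure.  The phantom's
  baked-in noise texture provides some interior signal that real
  tissue-contrast images may not.
* The affine stage assumes the centre-of-mass/ICP initialisation lands
  within the metric's basin of attraction; wildly different fields of view
  are out of scope.
* No iterative atlas re-estimation (register-to-atlas-and-repeat): one
  reference-based pass plus unbiasing.
* 3D only; stationary velocities only; no GPU path.
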