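# bodyatlas

Population atlases are the standard way to compare individual medical
images against a reference: every subject is registered into a common
coordinate space, and the registered cohort is averaged into an anatomical
atlas (and per-structure probability maps).  For whole-body MRI this is
much harder than for brain imaging — body composition, organ position and
fat distribution vary enormously between people — so a single atlas is a
poor representation of everyone.  `bodyatlas` implements a complete,
tested pipeline for this setting, aimed at researchers working with
volumetric body MRI cohorts:

* **cohort partitioning** into six sex x BMI groups (normal [18.5, 25),
  overweight [25, 30), obese >= 30), with a healthy-subject filter
  (no cancer record, no self-reported disease, no operation history) and
  median-phenotype reference selection per group;
* **registration** of every subject to the group reference: intensity
  normalisation + automatic body masking, centre-of-mass/ICP rigid
  initialisation, a 12-dof affine stage, then diffeomorphic B-spline
  free-form deformation.  The deformable transform is a stationary
  velocity field integrated by scaling-and-squaring, minimising
  `D(F, M o phi) + lambda * R(v)` with a bending-energy regulariser over a
  multi-resolution pyramid — invertible and topology-preserving by
  construction;
* **atlas construction**: `A_init = (1/n) sum_i I_i o phi_i`, probabilistic
  label atlases from one-hot-encoded structures, and **unbiasing**
  `A_u = A_init o Phi` with `Phi = (1/n) sum_i phi_i^{-1}`, so the atlas
  reflects the population's mean geometry rather than the reference
  subject's;
* **evaluation**: per-organ Dice, 95th-percentile Hausdorff distance (mm),
  and the folding ratio (fraction of voxels with non-positive Jacobian
  determinant);
* **voxel-based morphometry**: Gaussian smoothing of atlas-space tissue
  maps, a per-voxel two-group GLM (pooled t -> signed z-scores),
  Benjamini-Hochberg FDR control with a corrected-p retention threshold.

Real whole-body cohorts are access-restricted, so the package includes a
phantom generator producing synthetic 3D bodies (background, body outline,
subcutaneous-fat shell, visceral-fat blobs, five organ ellipsoids) with
known ground-truth deformations and matching phenotype tables; every stage
of the pipeline is validated against this simulated truth.

## Worked example

Generate a phantom pair, register, and inspect the improvement:

```r
library(bodyatlas)

spec <- phantomSpec()                      # 64 x 48 x 96 voxels at 3 mm
tpl  <- makeTemplate(spec)                 # template body + 7-class labels
sub  <- sampleSubject(tpl, spec, seed = 7) # deformed subject, known truth

chain <- registerPair(tpl$volume, sub$volume)

mean(dicePerLabel(tpl$labels, sub$labels, 3:7))                    # pre
#> [1] 0.587
wA <- warpVolume(sub$labels, chain$affineField, "nearest")
mean(dicePerLabel(tpl$labels, wA, 3:7))                            # affine
#> [1] 0.869
wD <- warpVolume(sub$labels, chain$field, "nearest")
mean(dicePerLabel(tpl$labels, wD, 3:7))                            # FFD
#> [1] 0.952
chain$foldingRatio
#> [1] 0
```

The mean organ overlap (Dice over liver, spleen, pancreas and both
kidneys) rises from 0.59 before registration to 0.87 after the affine
stage and 0.95 after the deformable stage, with zero spatial folding —
the transform stays diffeomorphic.  Because the subject was generated from
the template with a known transform, the recovered field can also be
compared against the exact inverse of the truth (the test suite requires a
mean interior endpoint error below one voxel).

Building and unbiasing a small atlas:

```r
cohort <- makeCohort(n = 6, groups = "female-overweight", spec = spec,
                     seed = 1, dir = "cohort/")
cfg <- pipelineConfig("cohort/", "atlas/", group = "female-overweight")
runGroupPipeline(cfg)
# atlas/atlas_initial.nii.gz, atlas/atlas_unbiased.nii.gz,
# atlas/atlas_*_prob_<structure>.nii.gz, metrics_summary.csv, provenance.json
```

A thin command-line wrapper is installed as `exec/bodyatlas`
(`bodyatlas phantom ...`, `bodyatlas pipeline ...`, `bodyatlas vbm ...`).

## Package layout

* `R/` — S4 classes (`BodyVolume`, `LabelVolume`, `DisplacementField`,
  `AffineTransform3D`, `VelocityLattice`, `BodyAtlas`, `VoxelZMap`) and the
  module functions; `src/` — Rcpp kernels for resampling, field algebra,
  B-spline lattices, distance transforms and 3D morphology.
* `vignettes/bodyatlas-methods.Rmd` — the model, parameter and
  design-choice documentation.
* `tests/testthat/` — oracle-backed unit tests, property suites and the
  end-to-end acceptance tests.
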