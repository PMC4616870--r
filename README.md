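# FemFrac3D

Quantifying the *true* spatial displacement of "undisplaced" femoral neck
fractures (Garden stages I–II) from 3D surface models of the proximal femur.

On anteroposterior radiographs these fractures look undisplaced, but 3D
reconstructions show that many carry millimetre-scale translation and
substantial rotation of the head fragment — information that matters for
choosing between internal fixation and arthroplasty. FemFrac3D implements
the measurement protocol behind that observation as a tested, reusable R
pipeline, for orthopaedic researchers and methodologists working with
CT-derived bone surfaces, together with a synthetic femur-phantom generator
that provides ground-truth-controlled validation data.

## The measurement

Given a surface mesh of the fractured proximal femur and of the healthy
contralateral side (with head/neck/shaft region labels):

1. **Mirror** the fractured model across the sagittal plane (default
   `x = 0`), exploiting left–right skeletal symmetry.
2. **Superimpose** the mirrored model onto the healthy femur by rigid
   iterative-closest-point registration anchored on the **neck and shaft
   only** — the displaced head fragment must not drive the alignment.
3. **Locate the landmarks** on both models: the femoral head centre **c**
   as the centre of a robust least-squares "close-fit sphere" over the head
   region (fovea pit points excluded), and the deepest point of the fovea
   capitis **f** as the head vertex with maximal inward radial deficit
   `r − ‖p − c‖`.
4. **Report the displacement triple**

   - `d1 = ‖c_fractured − c_healthy‖` (mm), head-centre displacement,
   - `d2 = ‖f_fractured − f_healthy‖` (mm), fovea displacement,
   - `α  = ∠(c_f → f_f , c_h → f_h)` (degrees), the rotation of the
     centre-to-fovea line, in [0°, 180°].

The statistics layer provides Fleiss' kappa (multi-rater agreement),
Cohen's weighted kappa (two-occasion intra-rater agreement), the
Landis–Koch verbal scale, and an exact/approximate Mann-Whitney U test for
two-group comparisons of d1, d2 and α.

## Worked example

Generate a phantom pair whose head fragment is translated by (3, 4, 0) mm
and rotated 15° about an oblique axis, then measure it:

```r
library(FemFrac3D)

spec <- PhantomSpec(
  fragmentTransform = RigidTransform(
    rotationAboutAxis(c(0, 1, 0.3), 15), c(3, 4, 0)),
  seed = 42)
pair <- generatePhantomPair(spec)
pair$healthy
#> FemurModel (left): 9140 vertices [shaft:5103, neck:1475, head:2562]

res <- measureDisplacement(pair$fractured, pair$healthy)
res
#> DisplacementResult: d1 = 5.00 mm, d2 = 7.65 mm, alpha = 14.22 deg
#>   landmark source: fitted / fitted
res@registration
#> RegistrationReport: RMS 0.1216 mm after 2 iterations (converged)
res@sphereFits$healthy
#> SphereFitReport: r = 21.999 mm, RMS residual 0.05299 mm, 2541 points used (21 excluded, 3 iterations)
```

`d1` recovers the 5 mm translation magnitude exactly (rotation about the
head centre does not move the centre). `alpha` reads 14.22°, slightly below
the applied 15°, because the chosen axis is not exactly perpendicular to
the centre-to-fovea line — α measures only the rotation component that
moves that line, a documented property of the measure. The registration RMS
sits at the phantom's 0.05 mm vertex-noise floor, and the head sphere is
recovered at r ≈ 22 mm with the fovea pit points (21 of them) excluded by
the robust fit.

The statistics layer in one glance:

```r
mannWhitneyU(c(1, 2), c(3, 4))
#> GroupComparison (Mann-Whitney, exact): U = 0, p = 0.3333 (n1 = 2, n2 = 2)
fleissKappa(rbind(c("A","A","B"), c("A","B","B"), c("A","A","A")))
#> AgreementResult (fleiss): kappa = 0.0000 [slight]
landisKochCategory(0.937)
#> [1] "almost perfect"
```

A command-line front end (`inst/cli/femfrac3d`) exposes the same pipeline
as `measure`, `simulate`, `agreement` and `cohort-stats` subcommands driven
by YAML/JSON configs.

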