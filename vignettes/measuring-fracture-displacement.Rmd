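---
title: "Measuring 3D displacement of undisplaced femoral neck fractures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 3D displacement of undisplaced femoral neck fractures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Femoral neck fractures graded Garden I–II on an anteroposterior radiograph
are called "undisplaced", and treatment decisions are often made on that
basis. 3D reconstructions of routine CT scans tell a different story: the
head fragment frequently carries several millimetres of translation and
tens of degrees of rotation that a single projection cannot show. FemFrac3D
implements the measurement that makes this displacement quantitative, using
the patient's own healthy contralateral femur as the undisplaced reference.

## The measurement model

The protocol rests on three assumptions, made explicit here because they
bound what the numbers mean:

1. **Left–right symmetry.** The healthy contralateral femur, mirrored
   across the sagittal plane, is treated as the pre-fracture geometry of
   the injured side. Real femora are only approximately symmetric; the
   phantom generator exposes a `vertexNoiseSd` knob (independent per-side
   noise) precisely so that tests can probe this assumption.
2. **The unfractured anatomy aligns rigidly.** Superimposition is a rigid
   registration (no scaling — contralateral size equality is assumed), and
   it is anchored on the neck and shaft regions only. Anchoring on the head
   would absorb exactly the displacement being measured; the package
   therefore treats head-anchored registration as documented misuse.
3. **Two landmarks summarise the head.** The femoral head centre (centre of
   a least-squares sphere fitted to the head surface) and the deepest point
   of the fovea capitis define a directed line. Displacement is summarised
   by the distance between the two head centres (`d1`, mm), the distance
   between the two fovea points (`d2`, mm), and the angle between the two
   centre-to-fovea lines (`alpha`, degrees).

### What alpha can and cannot see

`alpha` is the angle between two directed lines, reported in [0°, 180°].
A rotation of the head fragment about an axis *perpendicular* to the
centre-to-fovea line rotates that line by the same angle, so `alpha`
recovers it. A rotation *about* the centre-to-fovea line itself leaves both
landmarks fixed and is invisible: `alpha ≈ 0` however large the spin. This
observability limit is inherent to any two-landmark measure; the test suite
asserts it as a property rather than hiding it. Directed (not axial) lines
are used so that rotations beyond 90° remain distinguishable — clinically
reported rotations reach 50°, which an axial convention would fold.

`d2` is computed after superimposition, exactly like `d1`, and is not
normalised by head radius. For a pure rotation by angle θ about the centre,
`d2 ≈ 2 (r − depth) sin(θ/2)`: the worked example in the README (15°
rotation plus 5 mm translation) shows how translation and rotation both
feed `d2`, which is why `d1` and `alpha` are the cleaner per-component
measures.

## Geometric components and their numerical choices

**Sphere fit.** The "close-fit sphere" minimises the geometric objective
Σ(‖p − c‖ − r)². A linear algebraic fit (Coope parameterisation) provides
the initial estimate; damped Gauss-Newton iteration refines it (cap 100
iterations, step tolerance 1e-12), and the implementation never returns a
worse RMS than its initialiser. Near-coplanar input (design-matrix
condition number above 1e8) is rejected as degenerate rather than returned
as a wild extrapolation. The robust mode drops points whose *inward* radial
deficit exceeds 0.5 mm and refits, up to 5 passes or until the exclusion
set stabilises. That threshold sits well below the shallowest plausible
fovea (≈ 1 mm) and well above surface noise at CT-mesh scale, so the pit is
excluded without starving the fit; on a 22 mm phantom head the exclusions
are exactly the pit vertices.

**Fovea localisation.** Among head vertices, the one with maximal inward
deficit, required to exceed 1 mm (configurable). Below that threshold the
pipeline raises a `foveaNotFound` condition instead of silently returning a
noise vertex — the caller can then supply a manual landmark, mirroring the
reviewer-driven workflow on real data. Exact ties break to the
lexicographically smallest coordinates, making results order-independent.

**Registration.** ICP with nearest-vertex correspondence (a compiled
brute-force search; at the few-thousand-point scale of the anchor regions
this is faster to run than any index is to build). Initialisation is
centroid + principal-axes alignment; the four proper-rotation sign choices
are scored by one correspondence pass and ties go to the identity-closest
rotation, making the start deterministic. Iteration stops when the RMS
change falls below 1e-6 mm or at 200 iterations; a configurable trimming
fraction (default 1.0, down to 0.8) is available to resist fracture-gap
outliers on real data. A final RMS above the sanity bound (default 5 mm)
yields a warning and `converged = FALSE` rather than an error, so cohort
runs survive an occasional pathological case visibly.

**Mirroring.** The sagittal plane defaults to `x = 0`; mesh files carry no
anatomical frame, so inputs must be expressed in a patient-like frame or
the plane must be overridden (the CLI exposes
`--mirror-plane px,py,pz,nx,ny,nz`). Because a change of mirror plane
differs from the default by a proper rigid motion that the subsequent
registration absorbs, the measured triple is insensitive to this choice —
the test suite asserts the stronger statement that a global rigid motion of
both inputs changes (d1, d2, alpha) by less than one part in 1e6.

**Units** are millimetres throughout; no unit metadata is read from mesh
files (STL has none).

## The phantom generator

`generatePhantomPair()` assembles a parametric proximal femur: a head
sphere (radius 22 mm) carrying a fovea pit (5 mm wide, 3 mm deep, smooth
cosine profile at the far pole of the neck axis), a neck cylinder (radius
14 mm, length 35 mm) at a 130° neck-shaft angle with 12° anteversion, and
a shaft cylinder (radius 15 mm, length 120 mm) — plausible adult anatomy.
The fractured side is the *exact mirror image* of the healthy side with a
known rigid transform applied to the head-region vertices about the head
centre, mimicking a subcapital fracture; the fracture plane is left as a
bare discontinuity (no overlap resolution), which is sufficient for
landmark-level measurement. Independent per-side Gaussian vertex noise
(default SD 0.05 mm) models contralateral asymmetry and measurement noise.
Everything is deterministic given the seed, and the generator emits exact
ground-truth landmarks and the applied world-frame transform.

What the phantom does **not** emulate: real cortical surface texture,
osteophytes, the greater/lesser trochanters, CT partial-volume and
segmentation artefacts, impaction deformity at the fracture site, or
genuine anatomical asymmetry beyond isotropic noise. Passing phantom tests
therefore demonstrates that the *measurement chain* is correct and
well-conditioned, not that segmentation-quality clinical meshes will reach
the same tolerances.

Default mesh resolution is a 1.5 mm target edge (≈ 9,000 vertices per
femur). Cohort simulations default to 3 mm (≈ 2,300 vertices): the
landmark measures are essentially resolution-independent on the phantom —
the same mesh vertices are picked on both sides, so discretisation cancels —
and the coarser meshes keep a 60-subject simulated cohort at a few seconds.

## Simulated cohorts

`simulateCohort()` draws per-subject fragment displacements: translation
magnitudes and rotation angles from folded-normal distributions |N(mean,
sd)| (magnitudes are non-negative while published group values are
mean ± SD, and the folded normal is the simplest distribution matching that
moment structure; the stated values are used as the pre-fold parameters).
Translation directions are uniform on the sphere; rotation axes are uniform
among directions perpendicular to the centre-to-fovea line, i.e. the
simulation generates only the rotation component the measure can observe.
The default two groups emulate an incomplete-fracture condition
(translation (3.69, 1.77) mm, rotation (4.91, 2.49)°) versus a complete
undisplaced condition (translation (7.16, 4.58) mm, rotation
(18.77, 9.10)°), 30 subjects per group. Group summaries report means, SDs
and the clinically quoted threshold fractions: d1 > 10 mm (strict),
10° ≤ alpha ≤ 50° (inclusive bounds, matching the phrasing "10° to 50°"),
alpha > 20° (strict).

## The statistics layer

Published reliability analyses name both Fleiss' kappa and weighted kappa;
rather than guess, the package implements both — Fleiss for the
five-reviewer inter-observer design, Cohen's weighted kappa (linear or
quadratic weights) for two-occasion intra-observer data. How continuous
landmark picks were turned into categories is not standardised anywhere;
`discretizePicks()` makes the analysis executable by labelling each pick
"agree"/"disagree" against the per-subject consensus (coordinate-wise
median) within a configurable tolerance radius, default 2 mm — about the
width of the fovea floor, the natural scale at which two picks mean the
same anatomical point. The Landis–Koch bands are applied with boundaries
belonging to the lower band (0.2 → "slight", …, 0.8 → "substantial"),
matching the inclusive printed ranges of the scale.

The Mann-Whitney U test uses midranks for ties; the exact two-sided p value
(full enumeration of rank arrangements, 2·min(P(U ≤ u), P(U ≥ u)) capped at
1) is used when n1 + n2 ≤ 12 and the data are tie-free, otherwise the
normal approximation with tie and continuity corrections. The enumeration
bound is deliberately small: beyond it the approximation is accurate to
well under 0.02 and the exact distribution buys nothing.

## Problem sizes used by the test suite

Unit and property tests run phantoms at 3–4 mm resolution; the end-to-end
validation tests use the default 1.5 mm study conditions. The cohort
calibration checks run 20 replicate cohorts of 30 + 30 subjects for the
null (identical groups, rejection fraction on alpha expected near the 5%
level) and 20 for the separated default conditions (rotation means ~1.3
pooled SD apart, rejection fraction expected near 1). `scripts/acceptance.R`
re-runs the same battery from scratch and writes the measured quantities as
JSON.

## Known limitations

- The mirror plane must be supplied (or inputs pre-aligned); the package
  does not estimate the sagittal plane from anatomy.
- Region labels (head/neck/shaft) are sidecar inputs, not computed; no
  automatic anatomical segmentation is attempted.
- `alpha` is blind to rotation about the centre-to-fovea axis (above).
- Rigid registration only: impaction-induced shortening or plastic
  deformity of the neck violates the model and will surface as elevated
  registration RMS rather than be corrected.
- PLY support is ASCII-only; STL (binary and ASCII) and OBJ cover the
  common export paths.
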