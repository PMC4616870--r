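Package: FemFrac3D
Title: 3D Displacement Measurement for Undisplaced Femoral Neck Fractures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the true spatial displacement of "undisplaced"
    (Garden I-II) femoral neck fractures from paired proximal-femur surface
    meshes. The fractured side is mirrored across the sagittal plane and
    rigidly superimposed onto the healthy contralateral femur by iterative
    closest point registration anchored on the neck and shaft; the femoral
    head centre is localised by robust least-squares sphere fitting and the
    deepest point of the fovea capitis by maximal inward radial deficit.
    Three displacement parameters are reported: d1 (distance between head
    centres, mm), d2 (distance between fovea points, mm) and alpha (angle
    between the centre-to-fovea lines, degrees). Includes a parametric
    synthetic femur-phantom generator with known ground-truth fragment
    transforms, cohort simulation, inter/intra-rater agreement statistics
    (Fleiss and weighted kappa with Landis-Koch interpretation) and an
    exact/approximate Mann-Whitney U test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'transforms.R'
    'mesh-io.R'
    'sphere-fit.R'
    'register.R'
    'pipeline.R'
    'kappa.R'
    'mann-whitney.R'
    'phantom.R'
    'cohort.R'
    'cli.R'
    'FemFrac3D-package.R'
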