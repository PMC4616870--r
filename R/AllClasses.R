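#' @import methods
NULL

.isFiniteMatrix <- function(x) is.matrix(x) && is.numeric(x) && all(is.finite(x))

#' TriangleMesh: a triangulated surface in millimetre coordinates
#'
#' The basic geometry carrier of the package: an n x 3 matrix of vertex
#' coordinates (mm) and an m x 3 integer matrix of 1-based face indices.
#' Validity requires finite coordinates, in-range face indices, no degenerate
#' face (three distinct vertices) and at least 4 vertices.
#'
#' @slot vertices numeric matrix, n x 3, millimetres.
#' @slot faces integer matrix, m x 3, 1-based vertex indices.
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix"))

setValidity("TriangleMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (!is.matrix(v) || ncol(v) != 3L) return("vertices must be an n x 3 matrix")
  if (nrow(v) < 4L) return("mesh must have at least 4 vertices")
  if (!all(is.finite(v))) return("vertex coordinates must all be finite")
  if (!is.matrix(f) || ncol(f) != 3L) return("faces must be an m x 3 matrix")
  if (nrow(f) < 1L) return("mesh must have at least one face")
  fi <- as.integer(f)
  if (any(is.na(fi)) || any(fi < 1L) || any(fi > nrow(v)))
    return("face index out of range [1, nVertices]")
  if (any(f[, 1L] == f[, 2L] | f[, 1L] == f[, 3L] | f[, 2L] == f[, 3L]))
    return("degenerate face: a face must reference three distinct vertices")
  TRUE
})

#' Construct a TriangleMesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @return A validated \linkS4class{TriangleMesh}.
#' @examples
#' tet <- TriangleMesh(rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1)),
#'                     rbind(c(1,3,2), c(1,2,4), c(1,4,3), c(2,3,4)))
#' @export
TriangleMesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L,
                     dimnames = NULL)
  faces <- matrix(as.integer(faces), ncol = 3L, dimnames = NULL)
  new("TriangleMesh", vertices = vertices, faces = faces)
}

#' FemurModel: a region-labelled proximal femur surface
#'
#' A \linkS4class{TriangleMesh} together with a side label and a per-vertex
#' anatomical region mask. Region coding follows the sidecar convention
#' 0 = shaft, 1 = neck, 2 = head.
#'
#' @slot mesh a \linkS4class{TriangleMesh}.
#' @slot side "left" or "right".
#' @slot regionMask integer vector, one label in \{0,1,2\} per vertex.
#' @export
setClass("FemurModel",
  representation(mesh = "TriangleMesh", side = "character",
                 regionMask = "integer"))

setValidity("FemurModel", function(object) {
  if (length(object@side) != 1L || !object@side %in% c("left", "right"))
    return("side must be \"left\" or \"right\"")
  n <- nrow(object@mesh@vertices)
  if (length(object@regionMask) != n)
    return("regionMask must have one label per vertex")
  if (any(is.na(object@regionMask)) || !all(object@regionMask %in% 0:2))
    return("region labels must cover all vertices with values in {0,1,2}")
  TRUE
})

#' Construct a FemurModel
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param side "left" or "right".
#' @param regionMask per-vertex region labels: integers in \{0,1,2\}
#'   (0 = shaft, 1 = neck, 2 = head) or a character vector with those names.
#' @return A validated \linkS4class{FemurModel}.
#' @export
FemurModel <- function(mesh, side, regionMask) {
  if (is.character(regionMask)) {
    regionMask <- c(shaft = 0L, neck = 1L, head = 2L)[regionMask]
  }
  new("FemurModel", mesh = mesh, side = side,
      regionMask = as.integer(regionMask))
}

.REGION_CODES <- c(shaft = 0L, neck = 1L, head = 2L)

#' LandmarkSet: named anatomical landmarks in mm
#'
#' Carries the two landmarks of the measurement protocol, the femoral head
#' centre and the deepest point of the fovea capitis, with their provenance.
#'
#' @slot points named list of finite 3-vectors (mm); recognised names are
#'   "head_center" and "fovea_deepest".
#' @slot source "fitted" (computed) or "manual" (reviewer pick).
#' @slot side "left" or "right".
#' @export
setClass("LandmarkSet",
  representation(points = "list", source = "character", side = "character"))

setValidity("LandmarkSet", function(object) {
  if (!object@source %in% c("fitted", "manual"))
    return("source must be \"fitted\" or \"manual\"")
  if (!object@side %in% c("left", "right"))
    return("side must be \"left\" or \"right\"")
  if (length(object@points)) {
    if (is.null(names(object@points)) || any(names(object@points) == ""))
      return("all landmark points must be named")
    for (p in object@points) {
      if (!is.numeric(p) || length(p) != 3L || !all(is.finite(p)))
        return("each landmark must be a finite 3-vector")
    }
    hc <- object@points[["head_center"]]
    fv <- object@points[["fovea_deepest"]]
    if (!is.null(hc) && !is.null(fv) && all(hc == fv))
      return("fovea_deepest must be distinct from head_center")
  }
  TRUE
})

#' Construct a LandmarkSet
#'
#' @param points named list of 3-vectors (mm), e.g.
#'   \code{list(head_center = c(0,0,0), fovea_deepest = c(20,0,5))}.
#' @param source "fitted" or "manual".
#' @param side "left" or "right".
#' @export
LandmarkSet <- function(points, source = "manual", side = "left") {
  points <- lapply(points, as.numeric)
  new("LandmarkSet", points = points, source = source, side = side)
}

#' Sphere: a fitted femoral-head sphere
#'
#' @slot center finite 3-vector (mm).
#' @slot radius positive scalar (mm).
#' @export
setClass("Sphere", representation(center = "numeric", radius = "numeric"))

setValidity("Sphere", function(object) {
  if (length(object@center) != 3L || !all(is.finite(object@center)))
    return("center must be a finite 3-vector")
  if (length(object@radius) != 1L || !is.finite(object@radius) ||
      object@radius <= 0)
    return("radius must be a positive finite scalar")
  TRUE
})

#' @rdname Sphere-class
#' @param center,radius sphere centre (3-vector, mm) and radius (mm).
#' @export
Sphere <- function(center, radius) {
  new("Sphere", center = as.numeric(center), radius = as.numeric(radius))
}

#' RigidTransform: proper rigid motion (rotation + translation)
#'
#' Carrier for superimposition results and for phantom ground truth.
#' Acts on row-vector point matrices as \code{p \%*\% t(R) + t}.
#'
#' @slot rotation 3 x 3 orthonormal matrix, determinant +1 (within 1e-9).
#' @slot translation 3-vector (mm).
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!.isFiniteMatrix(R) || any(dim(R) != c(3L, 3L)))
    return("rotation must be a finite 3 x 3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation must be orthonormal within 1e-9")
  if (abs(det(R) - 1) > 1e-9)
    return("rotation must have determinant +1 within 1e-9 (no reflection)")
  if (length(object@translation) != 3L || !all(is.finite(object@translation)))
    return("translation must be a finite 3-vector")
  TRUE
})

#' Construct a RigidTransform
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation 3-vector (mm). Defaults to zero.
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = matrix(as.numeric(rotation), 3L, 3L),
      translation = as.numeric(translation))
}

#' SphereFitReport: diagnostics of a least-squares sphere fit
#'
#' @slot sphere the fitted \linkS4class{Sphere}.
#' @slot rmsResidual root-mean-square radial residual (mm) over used points.
#' @slot nPointsUsed,nExcluded counts of points kept / dropped by the robust
#'   fovea-exclusion passes.
#' @slot iterations geometric-refinement iterations of the final pass.
#' @export
setClass("SphereFitReport",
  representation(sphere = "Sphere", rmsResidual = "numeric",
                 nPointsUsed = "integer", nExcluded = "integer",
                 iterations = "integer"))

setValidity("SphereFitReport", function(object) {
  if (object@rmsResidual < 0) return("rmsResidual must be >= 0")
  if (object@nPointsUsed < 4L) return("nPointsUsed must be >= 4")
  TRUE
})

#' RegistrationReport: diagnostics of rigid (ICP) superimposition
#'
#' @slot transform the recovered source-to-target \linkS4class{RigidTransform}.
#' @slot rmsError final RMS correspondence distance (mm).
#' @slot iterations ICP iterations run.
#' @slot converged TRUE when the RMS change fell below tolerance before the
#'   iteration cap.
#' @export
setClass("RegistrationReport",
  representation(transform = "RigidTransform", rmsError = "numeric",
                 iterations = "integer", converged = "logical"))

setValidity("RegistrationReport", function(object) {
  if (object@rmsError < 0) return("rmsError must be >= 0")
  TRUE
})

#' DisplacementResult: the d1 / d2 / alpha displacement triple
#'
#' Result of measuring one fractured/healthy femur pair: d1 is the distance
#' between femoral head centres after mirrored superimposition (mm), d2 the
#' distance between the deepest fovea points (mm), and alpha the angle between
#' the centre-to-fovea lines (degrees).
#'
#' @slot d1,d2 non-negative distances (mm).
#' @slot alpha angle in degrees, in [0, 180].
#' @slot landmarksHealthy,landmarksFracturedMirrored the landmarks used, the
#'   fractured-side set expressed in the healthy frame (after mirror +
#'   registration).
#' @slot registration the \linkS4class{RegistrationReport} of superimposition.
#' @slot sphereFits list of two \linkS4class{SphereFitReport}s
#'   (healthy, fractured), empty entries when manual landmarks were used.
#' @export
setClass("DisplacementResult",
  representation(d1 = "numeric", d2 = "numeric", alpha = "numeric",
                 landmarksHealthy = "LandmarkSet",
                 landmarksFracturedMirrored = "LandmarkSet",
                 registration = "RegistrationReport",
                 sphereFits = "list"))

setValidity("DisplacementResult", function(object) {
  if (object@d1 < 0 || object@d2 < 0) return("d1 and d2 must be >= 0")
  if (object@alpha < 0 || object@alpha > 180)
    return("alpha must lie in [0, 180] degrees")
  TRUE
})

#' AgreementResult: a chance-corrected agreement coefficient
#'
#' @slot kappa coefficient in [-1, 1].
#' @slot method "fleiss" or "cohen_weighted".
#' @slot weightScheme "none", "linear" or "quadratic".
#' @slot category Landis-Koch verbal label for the coefficient.
#' @export
setClass("AgreementResult",
  representation(kappa = "numeric", method = "character",
                 weightScheme = "character", category = "character"))

setValidity("AgreementResult", function(object) {
  if (object@kappa < -1 - 1e-12 || object@kappa > 1 + 1e-12)
    return("kappa must lie in [-1, 1]")
  if (!identical(object@category, landisKochCategory(object@kappa)))
    return("category label inconsistent with kappa")
  TRUE
})

#' GroupComparison: a two-sample Mann-Whitney U comparison
#'
#' @slot uStatistic U statistic of the first sample (count scale).
#' @slot pValue two-sided p value.
#' @slot method "exact" or "normal-approximation".
#' @slot n1,n2 group sizes.
#' @export
setClass("GroupComparison",
  representation(uStatistic = "numeric", pValue = "numeric",
                 method = "character", n1 = "integer", n2 = "integer"))

setValidity("GroupComparison", function(object) {
  if (object@uStatistic < 0 ||
      object@uStatistic > object@n1 * object@n2 + 1e-9)
    return("U must lie in [0, n1 * n2]")
  if (object@pValue < 0 || object@pValue > 1)
    return("p value must lie in [0, 1]")
  TRUE
})

#' PhantomSpec: parameters of the synthetic femur phantom
#'
#' Generative parameters of a paired proximal-femur phantom: a head sphere
#' with a fovea pit, a neck cylinder and a shaft cylinder assembled at the
#' stated neck-shaft and anteversion angles. The "fractured" side is the exact
#' mirror image of the healthy side with \code{fragmentTransform} applied to
#' the head-region vertices about the head centre (rotation about the centre,
#' then translation), mimicking a subcapital fracture.
#'
#' @slot headRadius,neckRadius,neckLength,shaftRadius,shaftLength geometry, mm.
#' @slot neckShaftAngle,anteversion degrees.
#' @slot foveaRadius,foveaDepth fovea pit lateral radius and depth, mm.
#' @slot meshResolution target edge length, mm.
#' @slot vertexNoiseSd per-coordinate Gaussian vertex noise, mm, drawn
#'   independently on each side (contralateral asymmetry).
#' @slot fragmentTransform head-fragment \linkS4class{RigidTransform}
#'   (about the fractured head centre).
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(headRadius = "numeric", neckRadius = "numeric",
                 neckLength = "numeric", shaftRadius = "numeric",
                 shaftLength = "numeric", neckShaftAngle = "numeric",
                 anteversion = "numeric", foveaRadius = "numeric",
                 foveaDepth = "numeric", meshResolution = "numeric",
                 vertexNoiseSd = "numeric", fragmentTransform = "RigidTransform",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  lens <- c(object@headRadius, object@neckRadius, object@neckLength,
            object@shaftRadius, object@shaftLength, object@foveaRadius,
            object@foveaDepth, object@meshResolution)
  if (any(!is.finite(lens)) || any(lens <= 0))
    return("all lengths must be positive and finite")
  if (object@foveaDepth >= object@headRadius)
    return("foveaDepth must be smaller than headRadius")
  if (object@neckShaftAngle <= 0 || object@neckShaftAngle >= 180 ||
      object@anteversion <= -180 || object@anteversion >= 180)
    return("angles must lie strictly inside (0, 180) degrees")
  if (object@vertexNoiseSd < 0) return("vertexNoiseSd must be >= 0")
  TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults are plausible adult proximal-femur anatomy: head radius 22 mm,
#' neck radius 14 mm / length 35 mm, shaft radius 15 mm / length 120 mm,
#' neck-shaft angle 130 degrees, anteversion 12 degrees, fovea pit 5 mm wide
#' and 3 mm deep, target mesh edge 1.5 mm, vertex noise SD 0.05 mm.
#'
#' @param headRadius,neckRadius,neckLength,shaftRadius,shaftLength mm.
#' @param neckShaftAngle,anteversion degrees.
#' @param foveaRadius,foveaDepth mm.
#' @param meshResolution target mesh edge length, mm.
#' @param vertexNoiseSd per-coordinate vertex noise SD, mm.
#' @param fragmentTransform \linkS4class{RigidTransform} applied to the head
#'   fragment about the fractured-side head centre; identity = no displacement.
#' @param seed integer seed making the phantom deterministic.
#' @return A validated \linkS4class{PhantomSpec}.
#' @export
PhantomSpec <- function(headRadius = 22, neckRadius = 14, neckLength = 35,
                        shaftRadius = 15, shaftLength = 120,
                        neckShaftAngle = 130, anteversion = 12,
                        foveaRadius = 5, foveaDepth = 3,
                        meshResolution = 1.5, vertexNoiseSd = 0.05,
                        fragmentTransform = RigidTransform(),
                        seed = 1L) {
  new("PhantomSpec", headRadius = headRadius, neckRadius = neckRadius,
      neckLength = neckLength, shaftRadius = shaftRadius,
      shaftLength = shaftLength, neckShaftAngle = neckShaftAngle,
      anteversion = anteversion, foveaRadius = foveaRadius,
      foveaDepth = foveaDepth, meshResolution = meshResolution,
      vertexNoiseSd = vertexNoiseSd, fragmentTransform = fragmentTransform,
      seed = as.integer(seed))
}

#' CohortSpec: parameters of a simulated two-group fracture cohort
#'
#' Per-group fragment displacement distributions: translation magnitude and
#' rotation angle are folded-normal (|N(mean, sd)|), translation directions
#' uniform on the sphere, rotation axes uniform among directions perpendicular
#' to the centre-to-fovea line (the component of rotation the angle measure
#' alpha can observe).
#'
#' @slot groupSizes integer vector (two groups).
#' @slot translationMean,translationSd per-group folded-normal parameters, mm.
#' @slot rotationMean,rotationSd per-group folded-normal parameters, degrees.
#' @slot phantom template \linkS4class{PhantomSpec} for every subject.
#' @slot seed master seed.
#' @export
setClass("CohortSpec",
  representation(groupSizes = "integer", translationMean = "numeric",
                 translationSd = "numeric", rotationMean = "numeric",
                 rotationSd = "numeric", phantom = "PhantomSpec",
                 seed = "integer"))

setValidity("CohortSpec", function(object) {
  k <- length(object@groupSizes)
  if (k != 2L) return("exactly two groups are supported")
  if (any(object@groupSizes < 1L)) return("group sizes must be >= 1")
  pars <- c(object@translationMean, object@translationSd,
            object@rotationMean, object@rotationSd)
  if (length(object@translationMean) != k || length(object@translationSd) != k ||
      length(object@rotationMean) != k || length(object@rotationSd) != k)
    return("distribution parameters must be given per group")
  if (any(!is.finite(pars)) || any(pars < 0))
    return("distribution parameters must be >= 0")
  TRUE
})

#' Construct a CohortSpec
#'
#' Defaults emulate the incomplete-fracture (Garden Ia) versus complete
#' undisplaced (Garden II) study conditions: translation-magnitude
#' folded-normal parameters (3.69, 1.77) vs (7.16, 4.58) mm and rotation-angle
#' parameters (4.91, 2.49) vs (18.77, 9.10) degrees, 30 subjects per group.
#' Cohort phantoms default to a 3 mm mesh resolution, a simulation-scale
#' choice that leaves the landmark measurements essentially unchanged (see the
#' vignette) while keeping large cohorts tractable.
#'
#' @param groupSizes integer vector of two group sizes.
#' @param translationMean,translationSd length-2 numeric, mm.
#' @param rotationMean,rotationSd length-2 numeric, degrees.
#' @param phantom template \linkS4class{PhantomSpec}.
#' @param seed master integer seed.
#' @return A validated \linkS4class{CohortSpec}.
#' @export
CohortSpec <- function(groupSizes = c(30L, 30L),
                       translationMean = c(3.69, 7.16),
                       translationSd = c(1.77, 4.58),
                       rotationMean = c(4.91, 18.77),
                       rotationSd = c(2.49, 9.10),
                       phantom = PhantomSpec(meshResolution = 3),
                       seed = 1L) {
  new("CohortSpec", groupSizes = as.integer(groupSizes),
      translationMean = as.numeric(translationMean),
      translationSd = as.numeric(translationSd),
      rotationMean = as.numeric(rotationMean),
      rotationSd = as.numeric(rotationSd),
      phantom = phantom, seed = as.integer(seed))
}
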