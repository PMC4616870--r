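#' @include AllClasses.R
NULL

#' Accessors for FemFrac3D objects
#'
#' Small accessor generics used across the package instead of direct slot
#' access: \code{vertices()} / \code{faces()} for meshes, \code{mesh()},
#' \code{side()} and \code{regionMask()} for femur models, \code{center()} /
#' \code{radius()} for spheres, \code{rotation()} / \code{translation()} for
#' rigid transforms, \code{landmarks()} for landmark sets.
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("faces", function(object) standardGeneric("faces"))
#' @rdname accessors
#' @export
setGeneric("mesh", function(object) standardGeneric("mesh"))
#' @rdname accessors
#' @export
setGeneric("side", function(object) standardGeneric("side"))
#' @rdname accessors
#' @export
setGeneric("regionMask", function(object) standardGeneric("regionMask"))
#' @rdname accessors
#' @export
setGeneric("center", function(object) standardGeneric("center"))
#' @rdname accessors
#' @export
setGeneric("radius", function(object) standardGeneric("radius"))
#' @rdname accessors
#' @export
setGeneric("rotation", function(object) standardGeneric("rotation"))
#' @rdname accessors
#' @export
setGeneric("translation", function(object) standardGeneric("translation"))
#' @rdname accessors
#' @export
setGeneric("landmarks", function(object) standardGeneric("landmarks"))

#' @rdname accessors
#' @export
setMethod("vertices", "TriangleMesh", function(object) object@vertices)
#' @rdname accessors
#' @export
setMethod("faces", "TriangleMesh", function(object) object@faces)
#' @rdname accessors
#' @export
setMethod("vertices", "FemurModel", function(object) object@mesh@vertices)
#' @rdname accessors
#' @export
setMethod("faces", "FemurModel", function(object) object@mesh@faces)
#' @rdname accessors
#' @export
setMethod("mesh", "FemurModel", function(object) object@mesh)
#' @rdname accessors
#' @export
setMethod("side", "FemurModel", function(object) object@side)
#' @rdname accessors
#' @export
setMethod("side", "LandmarkSet", function(object) object@side)
#' @rdname accessors
#' @export
setMethod("regionMask", "FemurModel", function(object) object@regionMask)
#' @rdname accessors
#' @export
setMethod("center", "Sphere", function(object) object@center)
#' @rdname accessors
#' @export
setMethod("radius", "Sphere", function(object) object@radius)
#' @rdname accessors
#' @export
setMethod("rotation", "RigidTransform", function(object) object@rotation)
#' @rdname accessors
#' @export
setMethod("translation", "RigidTransform", function(object) object@translation)
#' @rdname accessors
#' @export
setMethod("landmarks", "LandmarkSet", function(object) object@points)

#' Displacement-parameter accessors
#'
#' @param object a \linkS4class{DisplacementResult}.
#' @name displacement-accessors
NULL

#' @rdname displacement-accessors
#' @export
setGeneric("d1", function(object) standardGeneric("d1"))
#' @rdname displacement-accessors
#' @export
setGeneric("d2", function(object) standardGeneric("d2"))
#' @rdname displacement-accessors
#' @export
setGeneric("alpha3d", function(object) standardGeneric("alpha3d"))
#' @rdname displacement-accessors
#' @export
setMethod("d1", "DisplacementResult", function(object) object@d1)
#' @rdname displacement-accessors
#' @export
setMethod("d2", "DisplacementResult", function(object) object@d2)
#' @rdname displacement-accessors
#' @export
setMethod("alpha3d", "DisplacementResult", function(object) object@alpha)

#' Number of vertices / faces
#' @param object a \linkS4class{TriangleMesh} or \linkS4class{FemurModel}.
#' @name mesh-dims
NULL

#' @rdname mesh-dims
#' @export
setGeneric("nVertices", function(object) standardGeneric("nVertices"))
#' @rdname mesh-dims
#' @export
setGeneric("nFaces", function(object) standardGeneric("nFaces"))
#' @rdname mesh-dims
#' @export
setMethod("nVertices", "TriangleMesh", function(object) nrow(object@vertices))
#' @rdname mesh-dims
#' @export
setMethod("nFaces", "TriangleMesh", function(object) nrow(object@faces))
#' @rdname mesh-dims
#' @export
setMethod("nVertices", "FemurModel", function(object) nrow(object@mesh@vertices))
#' @rdname mesh-dims
#' @export
setMethod("nFaces", "FemurModel", function(object) nrow(object@mesh@faces))

setMethod("show", "TriangleMesh", function(object) {
  cat("TriangleMesh:", nVertices(object), "vertices,",
      nFaces(object), "faces (mm)\n")
})

setMethod("show", "FemurModel", function(object) {
  tab <- table(factor(object@regionMask, levels = 0:2,
                      labels = c("shaft", "neck", "head")))
  cat("FemurModel (", object@side, "): ", nVertices(object), " vertices [",
      paste(names(tab), as.integer(tab), sep = ":", collapse = ", "),
      "]\n", sep = "")
})

setMethod("show", "Sphere", function(object) {
  cat(sprintf("Sphere: center (%.3f, %.3f, %.3f) mm, radius %.3f mm\n",
              object@center[1], object@center[2], object@center[3],
              object@radius))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngle(object@rotation)
  cat(sprintf("RigidTransform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, object@translation[1], object@translation[2],
              object@translation[3]))
})

setMethod("show", "SphereFitReport", function(object) {
  cat(sprintf("SphereFitReport: r = %.3f mm, RMS residual %.4g mm, %d points used (%d excluded, %d iterations)\n",
              object@sphere@radius, object@rmsResidual, object@nPointsUsed,
              object@nExcluded, object@iterations))
})

setMethod("show", "RegistrationReport", function(object) {
  cat(sprintf("RegistrationReport: RMS %.4g mm after %d iterations (%s)\n",
              object@rmsError, object@iterations,
              if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "DisplacementResult", function(object) {
  cat(sprintf("DisplacementResult: d1 = %.2f mm, d2 = %.2f mm, alpha = %.2f deg\n",
              object@d1, object@d2, object@alpha))
  cat("  landmark source:", object@landmarksHealthy@source, "/",
      object@landmarksFracturedMirrored@source, "\n")
})

setMethod("show", "AgreementResult", function(object) {
  cat(sprintf("AgreementResult (%s%s): kappa = %.4f [%s]\n", object@method,
              if (object@weightScheme == "none") ""
              else paste0(", ", object@weightScheme),
              object@kappa, object@category))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison (Mann-Whitney, %s): U = %g, p = %.4g (n1 = %d, n2 = %d)\n",
              object@method, object@uStatistic, object@pValue,
              object@n1, object@n2))
})
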