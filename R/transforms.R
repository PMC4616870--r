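#' @include AllClasses.R
NULL

.asPoints <- function(p) {
  if (is.null(dim(p))) matrix(as.numeric(p), ncol = 3L) else p
}

#' Apply a rigid transform to points, a mesh or a femur model
#'
#' Points are treated as rows; the action is \code{p \%*\% t(R) + t}.
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @param x an n x 3 point matrix, a 3-vector, a \linkS4class{TriangleMesh}
#'   or a \linkS4class{FemurModel}.
#' @return Object of the same kind as \code{x}, transformed.
#' @export
applyTransform <- function(transform, x) {
  stopifnot(is(transform, "RigidTransform"))
  if (is(x, "FemurModel")) {
    m <- x@mesh
    m@vertices <- applyTransform(transform, m@vertices)
    return(new("FemurModel", mesh = m, side = x@side,
               regionMask = x@regionMask))
  }
  if (is(x, "TriangleMesh")) {
    x@vertices <- applyTransform(transform, x@vertices)
    return(x)
  }
  vec <- is.null(dim(x))
  p <- .asPoints(x)
  out <- p %*% t(transform@rotation) +
    rep(transform@translation, each = nrow(p))
  if (vec) as.numeric(out) else out
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying \code{first}, then
#' \code{second}.
#'
#' @param second,first \linkS4class{RigidTransform}s.
#' @export
composeTransforms <- function(second, first) {
  RigidTransform(second@rotation %*% first@rotation,
                 as.numeric(second@rotation %*% first@translation) +
                   second@translation)
}

#' Invert a rigid transform
#' @param transform a \linkS4class{RigidTransform}.
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  RigidTransform(Rt, -as.numeric(Rt %*% transform@translation))
}

#' Rotation about an axis (Rodrigues formula)
#'
#' @param axis 3-vector, normalised internally.
#' @param angleDeg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotationAboutAxis <- function(axis, angleDeg) {
  a <- as.numeric(axis)
  na <- sqrt(sum(a^2))
  if (!all(is.finite(a)) || na < 1e-12)
    stop("rotation axis must be a finite nonzero 3-vector")
  a <- a / na
  th <- angleDeg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3L, 3L)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation angle of a rotation matrix, in degrees
#' @param R 3 x 3 rotation matrix.
#' @export
rotationAngle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' A rigid transform acting about a pivot point
#'
#' Builds the world-frame transform whose action is "rotate by \code{rotation}
#' about \code{pivot}, then translate by \code{translation}" — the natural
#' parameterisation of a head-fragment displacement about the head centre.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation 3-vector (mm).
#' @param pivot 3-vector (mm) the rotation acts about.
#' @return A \linkS4class{RigidTransform}.
#' @export
transformAboutPoint <- function(rotation = diag(3), translation = c(0, 0, 0),
                                pivot = c(0, 0, 0)) {
  pivot <- as.numeric(pivot)
  RigidTransform(rotation,
                 pivot - as.numeric(rotation %*% pivot) +
                   as.numeric(translation))
}

#' Euclidean distance between two points (mm)
#'
#' @param a,b finite 3-vectors (mm).
#' @return Non-negative distance in mm.
#' @examples
#' pointDistance(c(0, 0, 0), c(3, 4, 0))  # 5
#' @export
pointDistance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 3L || length(b) != 3L || !all(is.finite(c(a, b))))
    stop("pointDistance: inputs must be finite 3-vectors")
  sqrt(sum((a - b)^2))
}

#' Angle between two directed lines, in degrees
#'
#' Computes arccos of the (clamped) dot product of the unit direction vectors
#' of the segments \code{uFrom -> uTo} and \code{vFrom -> vTo}. Directions are
#' used as given (directed lines), so the result lies in [0, 180] degrees.
#'
#' @param uFrom,uTo,vFrom,vTo finite 3-vectors (mm).
#' @return Angle in degrees in [0, 180].
#' @examples
#' angleBetweenLines(c(0,0,0), c(1,0,0), c(0,0,0), c(0,1,0))  # 90
#' @export
angleBetweenLines <- function(uFrom, uTo, vFrom, vTo) {
  u <- as.numeric(uTo) - as.numeric(uFrom)
  v <- as.numeric(vTo) - as.numeric(vFrom)
  if (!all(is.finite(c(u, v))))
    stop("angleBetweenLines: inputs must be finite 3-vectors")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu <= 1e-9 || nv <= 1e-9)
    stop("angleBetweenLines: zero-length segment (length <= 1e-9 mm)")
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Mirror plane specification
#'
#' A plane is given as a point on the plane and a unit normal. The default is
#' the sagittal-plane convention x = 0 used throughout the package for
#' contralateral mirroring.
#'
#' @param point 3-vector on the plane (mm).
#' @param normal 3-vector normal; normalised internally, rejected when its
#'   length is below 1e-9.
#' @return A list with components \code{point} and unit \code{normal}.
#' @export
mirrorPlane <- function(point = c(0, 0, 0), normal = c(1, 0, 0)) {
  point <- as.numeric(point); normal <- as.numeric(normal)
  if (length(point) != 3L || length(normal) != 3L ||
      !all(is.finite(c(point, normal))))
    stop("mirrorPlane: point and normal must be finite 3-vectors")
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-9) stop("mirrorPlane: normal must be a nonzero vector")
  list(point = point, normal = normal / nn)
}

.reflectPoints <- function(points, plane) {
  p <- .asPoints(points)
  n <- plane$normal
  d <- as.numeric(p %*% n) - sum(plane$point * n)
  p - 2 * outer(d, n)
}

#' Mirror a femur model across a plane
#'
#' Reflects every vertex across the plane, rewinds each face so outward
#' normals are preserved under the reflection, and flips the side label.
#' Applying the mirror twice restores the original model.
#'
#' @param model a \linkS4class{FemurModel} (or \linkS4class{TriangleMesh}).
#' @param plane a plane from \code{\link{mirrorPlane}}; default sagittal
#'   plane x = 0.
#' @return Mirrored object of the same class as \code{model}.
#' @export
mirrorMesh <- function(model, plane = mirrorPlane()) {
  plane <- mirrorPlane(plane$point, plane$normal)
  if (is(model, "FemurModel")) {
    m <- mirrorMesh(model@mesh, plane)
    return(new("FemurModel", mesh = m,
               side = if (model@side == "left") "right" else "left",
               regionMask = model@regionMask))
  }
  stopifnot(is(model, "TriangleMesh"))
  v <- .reflectPoints(model@vertices, plane)
  f <- model@faces[, c(1L, 3L, 2L), drop = FALSE]  # reflection flips winding
  new("TriangleMesh", vertices = v, faces = f)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a \linkS4class{TriangleMesh}.
#' @export
surfaceArea <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

# Run code under a local RNG stream without disturbing the caller's RNG.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
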