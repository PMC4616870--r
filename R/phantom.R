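#' @include AllClasses.R transforms.R
NULL

# Icosphere: subdivided icosahedron scaled to the requested radius.
.icosphere <- function(radius, level) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    uk <- !duplicated(key)
    mididx <- nrow(v) + match(key, key[uk])
    mids <- (v[e[uk, 1], , drop = FALSE] + v[e[uk, 2], , drop = FALSE]) / 2
    v <- rbind(v, mids)
    nf <- nrow(f)
    m12 <- mididx[seq_len(nf)]
    m23 <- mididx[nf + seq_len(nf)]
    m31 <- mididx[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  v <- v * (radius / sqrt(rowSums(v^2)))
  list(vertices = v, faces = f)
}

# Open cylinder from pointA to pointB (no caps), target edge length res.
.cylinderMesh <- function(pointA, pointB, radius, res) {
  axis <- pointB - pointA
  L <- sqrt(sum(axis^2))
  d <- axis / L
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * d) * d; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2], d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  nAround <- max(8L, ceiling(2 * pi * radius / res))
  nAlong <- max(2L, ceiling(L / res) + 1L)
  ang <- 2 * pi * (seq_len(nAround) - 1L) / nAround
  ring <- radius * (outer(cos(ang), e1) + outer(sin(ang), e2))
  zs <- seq(0, L, length.out = nAlong)
  v <- do.call(rbind, lapply(zs, function(z)
    ring + rep(pointA + z * d, each = nAround)))
  idx <- function(i, j) (i - 1L) * nAround + ((j - 1L) %% nAround) + 1L
  f <- do.call(rbind, lapply(seq_len(nAlong - 1L), function(i) {
    j <- seq_len(nAround)
    rbind(cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j)),
          cbind(idx(i, j + 1L), idx(i + 1L, j + 1L), idx(i + 1L, j)))
  }))
  list(vertices = v, faces = f)
}

.appendMesh <- function(a, b) {
  list(vertices = rbind(a$vertices, b$vertices),
       faces = rbind(a$faces, b$faces + nrow(a$vertices)))
}

# Direction of the femoral neck axis (unit, from shaft top toward the head)
# for a given spec: neck-shaft angle from the shaft (+z) axis, anteversion
# about it, medial along +x.
.neckDirection <- function(spec) {
  th <- (180 - spec@neckShaftAngle) * pi / 180
  d0 <- c(sin(th), 0, cos(th))
  as.numeric(rotationAboutAxis(c(0, 0, 1), spec@anteversion) %*% d0)
}

# The healthy-side phantom, noise-free, with analytic landmarks.
.buildBasePhantom <- function(spec) {
  res <- spec@meshResolution
  d <- .neckDirection(spec)
  shaftTop <- c(0, 0, 0)
  neckEnd <- shaftTop + spec@neckLength * d
  headCenter <- neckEnd + 0.5 * spec@headRadius * d

  level <- min(5L, max(1L, ceiling(log2(1.0515 * spec@headRadius / res))))
  head <- .icosphere(spec@headRadius, level)
  # carve the fovea pit: radial indentation with a smooth cosine profile,
  # deepest along the neck-axis (far-pole) direction
  u <- head$vertices / spec@headRadius
  s <- spec@headRadius * acos(pmax(-1, pmin(1, as.numeric(u %*% d))))
  depth <- ifelse(s < spec@foveaRadius,
                  spec@foveaDepth * cos(pi * s / (2 * spec@foveaRadius))^2, 0)
  head$vertices <- head$vertices * (1 - depth / spec@headRadius)
  head$vertices <- head$vertices + rep(headCenter, each = nrow(head$vertices))

  neck <- .cylinderMesh(shaftTop, neckEnd, spec@neckRadius, res)
  shaft <- .cylinderMesh(c(0, 0, -spec@shaftLength), shaftTop,
                         spec@shaftRadius, res)

  m <- .appendMesh(shaft, .appendMesh(neck, head))
  mask <- c(rep(0L, nrow(shaft$vertices)), rep(1L, nrow(neck$vertices)),
            rep(2L, nrow(head$vertices)))
  list(mesh = TriangleMesh(m$vertices, m$faces), mask = mask,
       headCenter = headCenter,
       fovea = headCenter + (spec@headRadius - spec@foveaDepth) * d,
       neckDir = d)
}

#' Generate a paired femur phantom with known head-fragment displacement
#'
#' Builds a healthy proximal-femur surface (head sphere with a fovea pit,
#' neck cylinder, shaft cylinder, region-labelled) and its exact mirror image
#' as the "fractured" contralateral side, then applies the given
#' \code{fragmentTransform} to the fractured head-region vertices about the
#' fractured head centre (rotation about the centre, then translation) —
#' a subcapital fracture with perfect underlying left-right symmetry.
#' Independent per-side vertex noise models contralateral asymmetry.
#' Deterministic given the seed.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A list: \code{fractured} and \code{healthy}
#'   (\linkS4class{FemurModel}s, right and left), and \code{groundTruth} with
#'   the applied world-frame fragment transform and exact
#'   \linkS4class{LandmarkSet}s for both sides.
#' @export
generatePhantomPair <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  base <- .buildBasePhantom(spec)
  nv <- nrow(base$mesh@vertices)

  plane <- mirrorPlane()                       # sagittal plane x = 0
  healthyModel <- FemurModel(base$mesh, "left", base$mask)
  mirroredModel <- mirrorMesh(healthyModel, plane)   # becomes "right"

  headCenterF <- .reflectPoints(base$headCenter, plane)[1, ]
  foveaF0 <- .reflectPoints(base$fovea, plane)[1, ]
  worldTf <- transformAboutPoint(spec@fragmentTransform@rotation,
                                 spec@fragmentTransform@translation,
                                 pivot = headCenterF)
  vF <- mirroredModel@mesh@vertices
  headIdx <- mirroredModel@regionMask == 2L
  vF[headIdx, ] <- applyTransform(worldTf, vF[headIdx, , drop = FALSE])

  noise <- .withSeed(spec@seed, list(
    h = matrix(stats::rnorm(3 * nv, sd = spec@vertexNoiseSd), ncol = 3L),
    f = matrix(stats::rnorm(3 * nv, sd = spec@vertexNoiseSd), ncol = 3L)))

  healthyMesh <- base$mesh
  healthyMesh@vertices <- healthyMesh@vertices + noise$h
  fracturedMesh <- mirroredModel@mesh
  fracturedMesh@vertices <- vF + noise$f

  list(
    fractured = FemurModel(fracturedMesh, "right", mirroredModel@regionMask),
    healthy = FemurModel(healthyMesh, "left", base$mask),
    groundTruth = list(
      fragmentTransform = spec@fragmentTransform,
      worldTransform = worldTf,
      landmarksHealthy = LandmarkSet(
        list(head_center = base$headCenter, fovea_deepest = base$fovea),
        source = "manual", side = "left"),
      landmarksFractured = LandmarkSet(
        list(head_center = applyTransform(worldTf, headCenterF),
             fovea_deepest = applyTransform(worldTf, foveaF0)),
        source = "manual", side = "right"),
      neckDirection = base$neckDir))
}

#' Export a phantom pair to disk
#'
#' Writes the two meshes (binary STL or ASCII PLY), their region masks and a
#' ground-truth landmark/transform JSON.
#'
#' @param pair result of \code{\link{generatePhantomPair}}.
#' @param dir output directory (created if needed).
#' @param format "stl" or "ply".
#' @return Invisibly, the vector of files written.
#' @export
exportPhantomPair <- function(pair, dir, format = c("stl", "ply")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    fractured = file.path(dir, paste0("fractured.", format)),
    healthy = file.path(dir, paste0("healthy.", format)),
    fractured_mask = file.path(dir, "fractured_mask.txt"),
    healthy_mask = file.path(dir, "healthy_mask.txt"),
    ground_truth = file.path(dir, "ground_truth.json"))
  writeMesh(pair$fractured@mesh, files[["fractured"]], format)
  writeMesh(pair$healthy@mesh, files[["healthy"]], format)
  writeRegionMask(pair$fractured@regionMask, files[["fractured_mask"]])
  writeRegionMask(pair$healthy@regionMask, files[["healthy_mask"]])
  gt <- pair$groundTruth
  jsonlite::write_json(list(
    fragment_rotation = gt$fragmentTransform@rotation,
    fragment_translation = gt$fragmentTransform@translation,
    landmarks_healthy = gt$landmarksHealthy@points,
    landmarks_fractured = gt$landmarksFractured@points),
    files[["ground_truth"]], auto_unbox = TRUE, digits = NA)
  invisible(files)
}
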