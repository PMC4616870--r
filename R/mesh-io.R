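#' @include AllClasses.R transforms.R
NULL

# Merge exactly coincident vertices (STL stores a triangle soup).
.mergeVertices <- function(v, f) {
  key <- paste(v[, 1], v[, 2], v[, 3], sep = "|")
  first <- !duplicated(key)
  remap <- match(key, key[first])
  list(vertices = v[first, , drop = FALSE],
       faces = matrix(remap[f], ncol = 3L))
}

.sniffFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("stl", "ply", "obj")) return(ext)
  stop("cannot sniff mesh format of '", path,
       "'; pass format = \"stl\", \"ply\" or \"obj\"")
}

.isBinarySTL <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb"); on.exit(close(con))
  head <- readBin(con, "raw", n = 84L)
  if (length(head) < 84L) return(FALSE)
  ntri <- readBin(head[81:84], "integer", size = 4L, endian = "little")
  if (!is.na(ntri) && sz == 84 + 50 * as.numeric(ntri)) return(TRUE)
  !identical(rawToChar(head[1:5]), "solid")
}

.readSTL <- function(path) {
  if (.isBinarySTL(path)) {
    con <- file(path, "rb"); on.exit(close(con))
    readBin(con, "raw", n = 80L)
    ntri <- readBin(con, "integer", size = 4L, endian = "little")
    if (is.na(ntri) || ntri < 1L) stop("STL file '", path, "' is empty")
    recs <- readBin(con, "raw", n = 50L * ntri)
    if (length(recs) < 50L * ntri)
      stop("binary STL '", path, "' is truncated")
    # bytes 13..48 of each 50-byte record hold the 9 vertex float32s
    off <- rep((seq_len(ntri) - 1L) * 50L, each = 36L)
    idx <- off + rep(13:48, times = ntri)
    vals <- readBin(recs[idx], "numeric", size = 4L, n = 9L * ntri,
                    endian = "little")
    v <- matrix(vals, ncol = 3L, byrow = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (!length(vl)) stop("no vertices found in ASCII STL '", path, "'")
    toks <- strsplit(trimws(vl), "\\s+")
    v <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3L)))
    if (nrow(v) %% 3L != 0L)
      stop("ASCII STL '", path, "' has a vertex count not divisible by 3")
  }
  f <- matrix(seq_len(nrow(v)), ncol = 3L, byrow = TRUE)
  m <- .mergeVertices(v, f)
  TriangleMesh(m$vertices, m$faces)
}

.readPLY <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply")
    stop("'", path, "' is not a PLY file")
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("PLY '", path, "' has no end_header")
  header <- trimws(lines[seq_len(endh)])
  fmt <- grep("^format ", header, value = TRUE)
  if (!length(fmt) || !grepl("ascii", fmt[1]))
    stop("only ASCII PLY is supported (got: ", fmt[1], ")")
  nv <- as.integer(sub("^element vertex ", "",
                       grep("^element vertex ", header, value = TRUE)[1]))
  nf <- as.integer(sub("^element face ", "",
                       grep("^element face ", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("PLY '", path, "' missing vertex/face elements")
  body <- trimws(lines[(endh + 1L):length(lines)])
  body <- body[nzchar(body)]
  vt <- strsplit(body[seq_len(nv)], "\\s+")
  v <- t(vapply(vt, function(t) as.numeric(t[1:3]), numeric(3L)))
  ft <- strsplit(body[nv + seq_len(nf)], "\\s+")
  f <- t(vapply(ft, function(t) {
    cnt <- as.integer(t[1])
    if (cnt != 3L) stop("only triangular PLY faces are supported")
    as.integer(t[2:4]) + 1L
  }, integer(3L)))
  TriangleMesh(v, f)
}

.readOBJ <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl) || !length(fl))
    stop("OBJ '", path, "' contains no vertices or no faces")
  v <- t(vapply(strsplit(vl, "\\s+"),
                function(t) as.numeric(t[2:4]), numeric(3L)))
  f <- t(vapply(strsplit(fl, "\\s+"), function(t) {
    if (length(t) != 4L) stop("only triangular OBJ faces are supported")
    as.integer(sub("/.*$", "", t[2:4]))
  }, integer(3L)))
  TriangleMesh(v, f)
}

#' Read a surface mesh (STL, PLY or OBJ)
#'
#' Reads a triangulated surface; coordinates are taken to be millimetres
#' (mesh formats carry no unit metadata). STL may be binary or ASCII and its
#' triangle soup is welded back into shared vertices; PLY is ASCII; OBJ uses
#' v/f records. The returned mesh is validated (finite coordinates, in-range
#' indices, no degenerate faces).
#'
#' @param path file path.
#' @param format "stl", "ply" or "obj"; sniffed from the extension when
#'   omitted.
#' @return A \linkS4class{TriangleMesh}.
#' @export
readMesh <- function(path, format = c("auto", "stl", "ply", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mesh file not found: '", path, "'")
  if (format == "auto") format <- .sniffFormat(path)
  switch(format,
         stl = .readSTL(path),
         ply = .readPLY(path),
         obj = .readOBJ(path))
}

.writeSTLBinary <- function(mesh, path) {
  v <- mesh@vertices; f <- mesh@faces
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(raw(80L), con)
  ntri <- nrow(f)
  writeBin(ntri, con, size = 4L, endian = "little")
  tri <- v[as.integer(t(f)), , drop = FALSE]          # 3*ntri rows
  vals <- matrix(0, 12L, ntri)                        # normal + 3 vertices
  vals[4:12, ] <- t(tri)
  fl <- writeBin(as.numeric(vals), raw(), size = 4L, endian = "little")
  out <- raw(50L * ntri)
  off <- rep((seq_len(ntri) - 1L) * 50L, each = 48L)
  out[off + rep(1:48, times = ntri)] <- fl
  writeBin(out, con)
}

.writeSTLAscii <- function(mesh, path) {
  v <- mesh@vertices; f <- mesh@faces
  con <- file(path, "wt"); on.exit(close(con))
  writeLines("solid mesh", con)
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    writeLines(c(" facet normal 0 0 0", "  outer loop",
                 sprintf("   vertex %.9e %.9e %.9e",
                         tri[, 1], tri[, 2], tri[, 3]),
                 "  endloop", " endfacet"), con)
  }
  writeLines("endsolid mesh", con)
}

#' Write a surface mesh (STL, PLY or OBJ)
#'
#' @param mesh a valid \linkS4class{TriangleMesh}.
#' @param path output path.
#' @param format "stl", "ply" or "obj"; sniffed from the extension when
#'   omitted. PLY and OBJ are ASCII; STL defaults to binary.
#' @param binary for STL only: binary (default) or ASCII.
#' @return Invisibly, \code{path}. The file round-trips through
#'   \code{\link{readMesh}} within 1e-6 mm (ASCII) or exactly (binary STL up
#'   to float32 storage).
#' @export
writeMesh <- function(mesh, path, format = c("auto", "stl", "ply", "obj"),
                      binary = TRUE) {
  stopifnot(is(mesh, "TriangleMesh"))
  validObject(mesh)
  format <- match.arg(format)
  if (format == "auto") format <- .sniffFormat(path)
  if (format == "stl") {
    if (binary) .writeSTLBinary(mesh, path) else .writeSTLAscii(mesh, path)
  } else if (format == "ply") {
    v <- mesh@vertices; f <- mesh@faces
    con <- file(path, "wt"); on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(v)),
                 "property float x", "property float y", "property float z",
                 paste("element face", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
               con)
  } else {
    v <- mesh@vertices; f <- mesh@faces
    con <- file(path, "wt"); on.exit(close(con))
    writeLines(sprintf("v %.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

#' Read a landmark set from JSON
#'
#' Expects a JSON object with keys \code{side}, and any of
#' \code{head_center} / \code{fovea_deepest} as 3-element arrays (mm);
#' unknown keys are ignored. A missing optional point is permitted — it only
#' becomes an error when an operation needs it.
#'
#' @param path JSON file path.
#' @return A validated \linkS4class{LandmarkSet} (source "manual" unless the
#'   file says otherwise).
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: '", path, "'")
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(doc)) stop("landmark JSON must be an object")
  pts <- doc[intersect(names(doc), c("head_center", "fovea_deepest"))]
  for (nm in names(pts)) {
    p <- as.numeric(pts[[nm]])
    if (length(p) != 3L || !all(is.finite(p)))
      stop("landmark '", nm, "' must be a finite 3-vector")
    pts[[nm]] <- p
  }
  LandmarkSet(points = pts,
              source = if (!is.null(doc$source)) doc$source else "manual",
              side = if (!is.null(doc$side)) doc$side else "left")
}

#' Write a landmark set to JSON
#' @param lms a \linkS4class{LandmarkSet}.
#' @param path output path.
#' @export
writeLandmarks <- function(lms, path) {
  stopifnot(is(lms, "LandmarkSet"))
  doc <- c(list(side = lms@side, source = lms@source), lms@points)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a per-vertex region mask
#'
#' Region masks are sidecar files with one integer per vertex
#' (0 = shaft, 1 = neck, 2 = head), either newline-delimited text or a JSON
#' array.
#'
#' @param path file path.
#' @param nVertices optional expected length; mismatch is an error.
#' @return Integer vector of region labels.
#' @export
readRegionMask <- function(path, nVertices = NULL) {
  if (!file.exists(path)) stop("region mask file not found: '", path, "'")
  txt <- trimws(readLines(path, warn = FALSE))
  txt <- txt[nzchar(txt)]
  lab <- if (length(txt) && startsWith(txt[1], "["))
    as.integer(jsonlite::fromJSON(paste(txt, collapse = "")))
  else as.integer(txt)
  if (any(is.na(lab)) || !all(lab %in% 0:2))
    stop("region mask labels must be integers in {0, 1, 2}")
  if (!is.null(nVertices) && length(lab) != nVertices)
    stop("region mask has ", length(lab), " labels but the mesh has ",
         nVertices, " vertices")
  lab
}

#' Write a per-vertex region mask (newline-delimited integers)
#' @param mask integer vector of labels in \{0,1,2\}.
#' @param path output path.
#' @export
writeRegionMask <- function(mask, path) {
  writeLines(as.character(as.integer(mask)), path)
  invisible(path)
}
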