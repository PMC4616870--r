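test_that("mesh validation rejects constructed invariant violations", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  expect_s4_class(TriangleMesh(v, f), "TriangleMesh")
  expect_error(TriangleMesh(v, rbind(f, c(1, 2, 9))), "out of range")
  expect_error(TriangleMesh(rbind(v[1:3, ], c(NaN, 0, 0)), f), "finite")
  expect_error(TriangleMesh(v, rbind(f, c(1, 1, 2))), "degenerate")
  expect_error(TriangleMesh(v[1:3, ], f[1, , drop = FALSE]), "at least 4")
})

test_that("binary STL round-trips a tetrahedron with identical vertex multiset", {
  path <- withr::local_tempfile(fileext = ".stl")
  writeMesh(tetraMesh(), path, binary = TRUE)
  m <- readMesh(path)
  expect_equal(nVertices(m), 4L)
  expect_equal(nFaces(m), 4L)
  key <- function(v) sort(apply(v, 1, paste, collapse = ","))
  expect_identical(key(vertices(m)), key(vertices(tetraMesh())))
})

test_that("ASCII STL, PLY and OBJ round-trip within 1e-6 mm", {
  set.seed(5)
  base <- tetraMesh()
  base@vertices <- base@vertices + matrix(runif(12, -3, 3), 4, 3)
  for (fmt in c("stl", "ply", "obj")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    writeMesh(base, path, binary = FALSE)
    m <- readMesh(path)
    # welding may reorder vertices for STL; compare sorted coordinate rows
    a <- vertices(m)[order(vertices(m)[, 1], vertices(m)[, 2]), ]
    b <- vertices(base)[order(vertices(base)[, 1], vertices(base)[, 2]), ]
    expect_lt(max(abs(a - b)), 1e-6)
    expect_equal(nFaces(m), nFaces(base))
  }
})

test_that("format sniffing and error paths work", {
  expect_error(readMesh("no/such/file.stl"), "not found")
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines("junk", bad)
  expect_error(readMesh(bad), "sniff")
  ply <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 1",
               "property list uchar int vertex_indices", "end_header",
               "0 0 0", "1 0 0", "0 1 0", "0 0 1", "3 0 1 9"), ply)
  expect_error(readMesh(ply), "out of range")
})

test_that("landmark JSON reading is lenient but validated", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"side":"left","fovea_deepest":[10,0,0],"head_center":[0,0,0],"extra_key":42}',
             path)
  lms <- readLandmarks(path)
  expect_s4_class(lms, "LandmarkSet")
  expect_setequal(names(landmarks(lms)), c("head_center", "fovea_deepest"))
  expect_equal(landmarks(lms)$fovea_deepest, c(10, 0, 0))

  writeLines('{"side":"left","fovea_deepest":[1,2,3],"head_center":[1,2,3]}',
             path)
  expect_error(readLandmarks(path), "distinct")
  writeLines('{"side":"left","head_center":[1,2,null]}', path)
  expect_error(readLandmarks(path), "finite")
})

test_that("landmark sets round-trip through JSON", {
  lms <- LandmarkSet(list(head_center = c(0.5, -2, 3),
                          fovea_deepest = c(19.25, -2, 3)),
                     source = "fitted", side = "right")
  path <- withr::local_tempfile(fileext = ".json")
  writeLandmarks(lms, path)
  back <- readLandmarks(path)
  expect_equal(landmarks(back), landmarks(lms))
  expect_identical(side(back), "right")
})

test_that("region masks parse from text and JSON forms with validation", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0", "1", "2", "2"), path)
  expect_identical(readRegionMask(path), c(0L, 1L, 2L, 2L))
  writeLines("[0, 1, 2, 2]", path)
  expect_identical(readRegionMask(path), c(0L, 1L, 2L, 2L))
  expect_error(readRegionMask(path, nVertices = 7), "7 vertices")
  writeLines(c("0", "5"), path)
  expect_error(readRegionMask(path), "\\{0, 1, 2\\}")
})
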