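test_that("phantom generation is deterministic given the seed", {
  a <- generatePhantomPair(coarseSpec(seed = 99))
  b <- generatePhantomPair(coarseSpec(seed = 99))
  expect_identical(vertices(a$healthy), vertices(b$healthy))
  expect_identical(vertices(a$fractured), vertices(b$fractured))
  c <- generatePhantomPair(coarseSpec(seed = 100))
  expect_false(identical(vertices(a$healthy), vertices(c$healthy)))
})

test_that("phantom generation leaves the caller's RNG stream untouched", {
  set.seed(1234)
  before <- .Random.seed
  invisible(generatePhantomPair(coarseSpec(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("generated meshes pass validation and carry complete region masks", {
  pair <- cachedPair("coarse-noisy", coarseSpec())
  for (m in list(pair$healthy, pair$fractured)) {
    expect_true(validObject(m))
    expect_length(regionMask(m), nVertices(m))
    expect_true(all(0:2 %in% regionMask(m)))
  }
  expect_identical(side(pair$healthy), "left")
  expect_identical(side(pair$fractured), "right")
})

test_that("the healthy and fractured sides are exact mirror images under identity transform", {
  pair <- generatePhantomPair(coarseSpec(vertexNoiseSd = 0, seed = 1))
  mirroredBack <- mirrorMesh(pair$fractured)
  expect_lt(max(abs(vertices(mirroredBack) - vertices(pair$healthy))), 1e-12)
  expect_lt(abs(surfaceArea(mesh(pair$fractured)) -
                  surfaceArea(mesh(pair$healthy))) /
              surfaceArea(mesh(pair$healthy)), 1e-9)
})

test_that("ground-truth landmarks agree with the constructed anatomy", {
  pair <- cachedPair("coarse-noisy", coarseSpec())
  gtH <- landmarks(pair$groundTruth$landmarksHealthy)
  hc <- locateHeadCenter(pair$healthy)
  expect_lt(pointDistance(center(hc$sphere), gtH$head_center), 0.1)
  # the fovea pit bottom sits headRadius - foveaDepth from the centre
  expect_equal(pointDistance(gtH$fovea_deepest, gtH$head_center),
               22 - 3, tolerance = 1e-9)
})

test_that("the fragment transform moves the ground-truth fractured landmarks", {
  tf <- RigidTransform(diag(3), c(3, 4, 0))
  pair <- generatePhantomPair(coarseSpec(fragmentTransform = tf, seed = 12))
  gtF <- landmarks(pair$groundTruth$landmarksFractured)
  null <- generatePhantomPair(coarseSpec(seed = 12))
  gt0 <- landmarks(null$groundTruth$landmarksFractured)
  expect_equal(pointDistance(gtF$head_center, gt0$head_center), 5,
               tolerance = 1e-9)
  expect_equal(pointDistance(gtF$fovea_deepest, gt0$fovea_deepest), 5,
               tolerance = 1e-9)
})

test_that("invalid phantom specs are rejected", {
  expect_error(PhantomSpec(headRadius = -1), "positive")
  expect_error(PhantomSpec(foveaDepth = 25), "smaller than headRadius")
  expect_error(PhantomSpec(neckShaftAngle = 200), "0, 180")
})

test_that("phantom pairs export to disk and read back consistently", {
  dir <- withr::local_tempdir()
  pair <- cachedPair("coarse-noisy", coarseSpec())
  files <- exportPhantomPair(pair, dir, format = "stl")
  expect_true(all(file.exists(files)))
  m <- readMesh(files[["healthy"]])
  expect_s4_class(m, "TriangleMesh")
  # binary STL stores float32: agreement to float precision of ~20 mm coords
  expect_lt(max(abs(sort(vertices(m)[, 3]) -
                      sort(vertices(pair$healthy)[, 3]))), 1e-4)
  mask <- readRegionMask(files[["healthy_mask"]])
  expect_identical(mask, regionMask(pair$healthy))
  gt <- jsonlite::fromJSON(files[["ground_truth"]])
  expect_equal(as.numeric(gt$landmarks_healthy$head_center),
               landmarks(pair$groundTruth$landmarksHealthy)$head_center)
})
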