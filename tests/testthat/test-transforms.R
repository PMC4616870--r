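test_that("mirroring is an involution and an isometry", {
  set.seed(11)
  m <- tetraMesh()
  m@vertices <- m@vertices + matrix(runif(12, -5, 5), 4, 3)
  model <- FemurModel(m, "left", c(0L, 1L, 2L, 2L))
  pl <- mirrorPlane(c(0.5, -1, 2), c(1, 2, -1))
  mm <- mirrorMesh(model, pl)
  expect_identical(side(mm), "right")
  back <- mirrorMesh(mm, pl)
  expect_lt(max(abs(vertices(back) - vertices(model))), 1e-12)
  expect_identical(side(back), "left")
  # isometry: surface area and pairwise distances preserved
  expect_lt(abs(surfaceArea(mesh(mm)) - surfaceArea(m)) / surfaceArea(m), 1e-9)
  dOrig <- dist(vertices(model)); dMir <- dist(vertices(mm))
  expect_lt(max(abs(dOrig - dMir) / dOrig), 1e-12)
})

test_that("mirroring across x = 0 flips the x coordinate", {
  m <- tetraMesh()
  m@vertices[2, ] <- c(3, 0, 0)
  mm <- mirrorMesh(m)
  expect_equal(vertices(mm)[2, ], c(-3, 0, 0))
})

test_that("mirrorPlane rejects a degenerate normal", {
  expect_error(mirrorPlane(normal = c(0, 0, 0)), "nonzero")
  expect_error(mirrorPlane(normal = c(1, NA, 0)), "finite")
})

test_that("angleBetweenLines matches known configurations", {
  o <- c(0, 0, 0)
  expect_equal(angleBetweenLines(o, c(1, 2, 3), o, c(1, 2, 3)), 0)
  expect_equal(angleBetweenLines(o, c(1, 0, 0), o, c(0, 1, 0)), 90)
  expect_equal(angleBetweenLines(o, c(1, 0, 0), o, c(1, 1, 0)), 45)
  # directed lines: opposite directions give 180, not 0
  expect_equal(angleBetweenLines(o, c(1, 0, 0), o, c(-1, 0, 0)), 180)
  expect_error(angleBetweenLines(o, o, o, c(1, 0, 0)), "zero-length")
})

test_that("angleBetweenLines is invariant under common rigid transforms", {
  set.seed(21)
  for (i in 1:20) {
    pts <- matrix(rnorm(12, sd = 5), 4, 3)
    a0 <- angleBetweenLines(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    tf <- RigidTransform(rotationAboutAxis(rnorm(3), runif(1, 0, 180)),
                         rnorm(3, sd = 20))
    q <- applyTransform(tf, pts)
    a1 <- angleBetweenLines(q[1, ], q[2, ], q[3, ], q[4, ])
    expect_equal(a1, a0, tolerance = 1e-9)
  }
})

test_that("pointDistance is Euclidean, symmetric and validated", {
  expect_equal(pointDistance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(pointDistance(c(1, 1, 1), c(1, 1, 1)), 0)
  a <- c(2, -1, 7); b <- c(-3, 0.5, 1)
  expect_equal(pointDistance(a, b), pointDistance(b, a))
  expect_error(pointDistance(c(Inf, 0, 0), b), "finite")
})

test_that("RigidTransform validity enforces proper orthonormal rotations", {
  expect_error(RigidTransform(matrix(1, 3, 3)), "orthonormal")
  expect_error(RigidTransform(diag(c(1, 1, -1))), "determinant")
  expect_error(RigidTransform(diag(3), c(1, NA, 0)), "finite")
})

test_that("transform composition, inversion and pivoting behave", {
  set.seed(31)
  A <- RigidTransform(rotationAboutAxis(rnorm(3), 33), rnorm(3))
  B <- RigidTransform(rotationAboutAxis(rnorm(3), -70), rnorm(3))
  p <- rnorm(3)
  expect_equal(applyTransform(composeTransforms(B, A), p),
               applyTransform(B, applyTransform(A, p)), tolerance = 1e-12)
  ident <- composeTransforms(invertTransform(A), A)
  expect_lt(rotationAngle(rotation(ident)), 1e-9)
  expect_lt(max(abs(translation(ident))), 1e-9)
  # a rotation about a pivot leaves the pivot fixed
  piv <- c(4, -2, 9)
  tf <- transformAboutPoint(rotationAboutAxis(c(1, 1, 0), 50), pivot = piv)
  expect_equal(applyTransform(tf, piv), piv, tolerance = 1e-12)
})

test_that("rotationAboutAxis and rotationAngle are consistent", {
  set.seed(41)
  for (ang in c(0.5, 15, 90, 179)) {
    R <- rotationAboutAxis(rnorm(3), ang)
    expect_equal(rotationAngle(R), ang, tolerance = 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})
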