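test_that("registering a model to itself yields the identity", {
  pair <- cachedPair("coarse-null", coarseSpec(vertexNoiseSd = 0))
  rep <- registerRigid(pair$healthy, pair$healthy)
  expect_true(rep@converged)
  expect_lt(rep@rmsError, 1e-9)
  expect_lt(rotationAngle(rotation(rep@transform)), 1e-3)
  expect_lt(max(abs(translation(rep@transform))), 1e-3)
})

test_that("a known applied rigid transform is recovered", {
  pair <- cachedPair("coarse-null", coarseSpec(vertexNoiseSd = 0))
  target <- pair$healthy
  tf <- RigidTransform(rotationAboutAxis(c(0.2, 1, -0.5), 14), c(6, -4, 9))
  source <- applyTransform(tf, target)
  rep <- registerRigid(source, target)
  # recovered transform must equal tf^-1
  resid <- composeTransforms(rep@transform, tf)
  expect_lt(rotationAngle(rotation(resid)), 0.01)
  expect_lt(max(abs(translation(resid))), 1e-3)
  expect_true(rep@converged)
})

test_that("registration is invariant to a common rigid motion of both models", {
  tfFrag <- RigidTransform(rotationAboutAxis(c(0, 0, 1), 10), c(2, 1, 0))
  pair <- cachedPair("coarse-disp",
                     coarseSpec(fragmentTransform = tfFrag, vertexNoiseSd = 0))
  src <- mirrorMesh(pair$fractured)
  r0 <- registerRigid(src, pair$healthy)
  g <- RigidTransform(rotationAboutAxis(c(1, 2, 3), 41), c(30, -5, 12))
  r1 <- registerRigid(applyTransform(g, src), applyTransform(g, pair$healthy))
  # relative transform g o T0 o g^-1 must match T1
  rel <- composeTransforms(g, composeTransforms(r0@transform,
                                                invertTransform(g)))
  resid <- composeTransforms(invertTransform(r1@transform), rel)
  expect_lt(rotationAngle(rotation(resid)), 0.01)
  expect_lt(max(abs(translation(resid))), 1e-3)
})

test_that("region selection is validated and head-only use still honours the contract", {
  pair <- cachedPair("coarse-null", coarseSpec(vertexNoiseSd = 0))
  expect_error(registerRigid(pair$healthy, pair$healthy,
                             regions = character(0)), "empty region")
  expect_error(registerRigid(pair$healthy, pair$healthy, trim = 0.5),
               "trim")
  # documented misuse: aligning on the displaced head alone still returns a
  # well-formed report (the pipeline itself never does this)
  tfFrag <- RigidTransform(rotationAboutAxis(c(0, 0, 1), 10), c(2, 1, 0))
  disp <- cachedPair("coarse-disp",
                     coarseSpec(fragmentTransform = tfFrag, vertexNoiseSd = 0))
  rep <- registerRigid(mirrorMesh(disp$fractured), disp$healthy,
                       regions = "head")
  expect_s4_class(rep, "RegistrationReport")
  expect_gte(rep@rmsError, 0)
})

test_that("an unreachable sanity bound flags non-convergence with a warning", {
  # with vertex noise the correspondence RMS cannot drop below the noise
  # floor, so a tiny sanity bound must trip the warning path
  pair <- cachedPair("coarse-noisy", coarseSpec())
  expect_warning(
    rep <- registerRigid(mirrorMesh(pair$fractured), pair$healthy,
                         sanityRms = 1e-6),
    "sanity bound")
  expect_false(rep@converged)
})
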