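# Shared fixtures and independent oracles, all built in code at test time.

tetraMesh <- function() {
  TriangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
}

# Points on (or near) a sphere; per-coordinate Gaussian noise.
spherePoints <- function(n, center = c(0, 0, 0), r = 1, sd = 0) {
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  p <- sweep(r * u, 2, center, "+")
  if (sd > 0) p <- p + matrix(rnorm(3 * n, sd = sd), ncol = 3)
  p
}

# Independent sphere-fit oracle: multi-start Nelder-Mead on the geometric
# least-squares objective, no shared code with fitSphere().
oracleSphereFit <- function(p) {
  obj <- function(th) {
    d <- sqrt(rowSums((p - rep(th[1:3], each = nrow(p)))^2))
    mean((d - th[4])^2)
  }
  ctr <- colMeans(p)
  r0 <- mean(sqrt(rowSums((p - rep(ctr, each = nrow(p)))^2)))
  starts <- list(c(ctr, r0),
                 c(ctr + c(0.4, -0.4, 0.4) * r0, 1.5 * r0),
                 c(ctr + c(-0.2, 0.3, -0.1) * r0, 0.6 * r0),
                 c(ctr + c(0.1, 0.1, -0.3) * r0, 1.2 * r0))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(maxit = 50000, reltol = 1e-15))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(center = best$par[1:3], radius = best$par[4])
}

# Independent Fleiss-kappa oracle: explicit pairwise-agreement counting.
fleissOracle <- function(m) {
  n <- nrow(m); R <- ncol(m)
  Pbar <- mean(vapply(seq_len(n), function(i) {
    agree <- 0L
    for (a in seq_len(R - 1)) for (b in (a + 1):R)
      agree <- agree + (m[i, a] == m[i, b])
    agree / choose(R, 2)
  }, numeric(1)))
  cats <- unique(as.vector(m))
  Pe <- sum(vapply(cats, function(k) mean(m == k), numeric(1))^2)
  (Pbar - Pe) / (1 - Pe)
}

# Independent weighted-kappa oracle: explicit double loop over category pairs.
weightedKappaOracle <- function(a, b, cats, scheme) {
  k <- length(cats)
  n <- length(a)
  wfun <- function(i, j) if (scheme == "linear") abs(i - j) / (k - 1)
                         else (i - j)^2 / (k - 1)^2
  num <- 0; den <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    pij <- sum(a == cats[i] & b == cats[j]) / n
    eij <- (sum(a == cats[i]) / n) * (sum(b == cats[j]) / n)
    num <- num + wfun(i, j) * pij
    den <- den + wfun(i, j) * eij
  }
  1 - num / den
}

# Axis perpendicular to the fractured-side centre-to-fovea line.
fracturedFoveaDir <- function(pair) pair$groundTruth$neckDirection * c(-1, 1, 1)

perpAxis <- function(dirF, seedVec = c(0.3, -1, 0.5)) {
  w <- seedVec - sum(seedVec * dirF) * dirF
  w / sqrt(sum(w^2))
}

# Phantom pairs are expensive at fine resolution: cache across tests.
.pairCache <- new.env(parent = emptyenv())
cachedPair <- function(key, spec) {
  if (is.null(.pairCache[[key]])) .pairCache[[key]] <- generatePhantomPair(spec)
  .pairCache[[key]]
}

coarseSpec <- function(...) PhantomSpec(meshResolution = 3, ...)

# One default-condition cohort simulation shared by several tests.
.cohortEnv <- new.env(parent = emptyenv())
.cohortCache <- function() {
  if (is.null(.cohortEnv$sim))
    .cohortEnv$sim <- simulateCohort(CohortSpec(seed = 11))
  .cohortEnv$sim
}

# Minimal valid DisplacementResult for summary-level tests.
fakeResult <- function(d1 = 1, d2 = 1, alpha = 1) {
  new("DisplacementResult", d1 = d1, d2 = d2, alpha = alpha,
      landmarksHealthy = LandmarkSet(
        list(head_center = c(0, 0, 0), fovea_deepest = c(1, 0, 0)),
        source = "fitted", side = "left"),
      landmarksFracturedMirrored = LandmarkSet(
        list(head_center = c(0, 0, 0), fovea_deepest = c(1, 0, 0)),
        source = "fitted", side = "right"),
      registration = new("RegistrationReport", transform = RigidTransform(),
                         rmsError = 0, iterations = 1L, converged = TRUE),
      sphereFits = list())
}

# Hemisphere surface model (upper half of an icosphere), head-labelled.
hemisphereModel <- function(center = c(0, 0, 0), r = 10, level = 3) {
  ico <- FemFrac3D:::.icosphere(r, level)
  keep <- ico$vertices[, 3] >= -1e-9
  idx <- which(keep)
  fkeep <- apply(ico$faces, 1, function(f) all(f %in% idx))
  remap <- match(seq_len(nrow(ico$vertices)), idx)
  v <- sweep(ico$vertices[idx, , drop = FALSE], 2, center, "+")
  f <- matrix(remap[ico$faces[fkeep, ]], ncol = 3)
  FemurModel(TriangleMesh(v, f), "left", rep(2L, nrow(v)))
}
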