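#' @include AllClasses.R phantom.R pipeline.R mann-whitney.R
NULL

.randomUnit <- function() {
  repeat {
    w <- stats::rnorm(3)
    n <- sqrt(sum(w^2))
    if (n > 1e-8) return(w / n)
  }
}

# Unit vector uniform among directions perpendicular to `axis`.
.randomPerp <- function(axis) {
  repeat {
    w <- stats::rnorm(3)
    w <- w - sum(w * axis) * axis
    n <- sqrt(sum(w^2))
    if (n > 1e-8) return(w / n)
  }
}

#' Theoretical mean of a folded normal |N(mean, sd)|
#'
#' Used for parameter-recovery checks against simulated cohorts.
#'
#' @param mean,sd parameters of the underlying normal.
#' @export
foldedNormalMean <- function(mean, sd) {
  if (sd == 0) return(abs(mean))
  sd * sqrt(2 / pi) * exp(-mean^2 / (2 * sd^2)) +
    mean * (1 - 2 * stats::pnorm(-mean / sd))
}

#' Simulate a two-group fracture cohort end to end
#'
#' For every subject a head-fragment displacement is drawn from the group's
#' distributions — translation magnitude and rotation angle folded-normal,
#' translation direction uniform on the sphere, rotation axis uniform among
#' directions perpendicular to the centre-to-fovea line (the rotation
#' component the angle measure can observe) — a paired phantom is generated,
#' and the full mirrored-superimposition measurement is run. Group summaries
#' and two-sample Mann-Whitney tests on d1, d2 and alpha are returned.
#' Reproducible under the master seed.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param keepPairs keep the generated phantom pairs in the result (memory!).
#' @return A list: \code{results} (list of
#'   \linkS4class{DisplacementResult}s), \code{groups} (labels "group1" /
#'   "group2"), \code{truth} (data.frame of drawn translation magnitudes and
#'   rotation angles), \code{summary} (from \code{\link{summarizeCohort}}),
#'   \code{tests} (named list of \linkS4class{GroupComparison} for d1, d2,
#'   alpha), and optionally \code{pairs}.
#' @export
simulateCohort <- function(spec, keepPairs = FALSE) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  k <- length(spec@groupSizes)
  draws <- .withSeed(spec@seed, {
    out <- list()
    for (g in seq_len(k)) {
      for (i in seq_len(spec@groupSizes[g])) {
        out[[length(out) + 1L]] <- list(
          group = g,
          tmag = abs(stats::rnorm(1, spec@translationMean[g],
                                  spec@translationSd[g])),
          tdir = .randomUnit(),
          rang = abs(stats::rnorm(1, spec@rotationMean[g],
                                  spec@rotationSd[g])),
          axisSeedVec = stats::rnorm(3),
          seed = sample.int(.Machine$integer.max - 1L, 1L))
      }
    }
    out
  })

  base <- spec@phantom
  # rotation axes must be perpendicular to the fractured-side fovea line,
  # which is the mirror image of the healthy neck-axis direction
  foveaDir <- .neckDirection(base)
  foveaDirF <- foveaDir * c(-1, 1, 1)

  runOne <- function(dr) {
    w <- dr$axisSeedVec
    w <- w - sum(w * foveaDirF) * foveaDirF
    n <- sqrt(sum(w^2))
    if (n < 1e-8) w <- c(foveaDirF[2], -foveaDirF[1], 0) else w <- w / n
    tf <- RigidTransform(rotationAboutAxis(w, dr$rang), dr$tmag * dr$tdir)
    ps <- base
    ps@fragmentTransform <- tf
    ps@seed <- as.integer(dr$seed)
    generatePhantomPair(ps)
  }

  pairs <- lapply(draws, runOne)
  results <- lapply(pairs, function(p)
    measureDisplacement(p$fractured, p$healthy))
  groups <- paste0("group", vapply(draws, `[[`, numeric(1), "group"))
  truth <- data.frame(
    group = groups,
    translation_mm = vapply(draws, `[[`, numeric(1), "tmag"),
    rotation_deg = vapply(draws, `[[`, numeric(1), "rang"))

  g1 <- groups == "group1"
  val <- function(f) vapply(results, f, numeric(1))
  tests <- list(
    d1 = mannWhitneyU(val(d1)[g1], val(d1)[!g1]),
    d2 = mannWhitneyU(val(d2)[g1], val(d2)[!g1]),
    alpha = mannWhitneyU(val(alpha3d)[g1], val(alpha3d)[!g1]))

  out <- list(results = results, groups = groups, truth = truth,
              summary = summarizeCohort(results, groups), tests = tests)
  if (keepPairs) out$pairs <- pairs
  out
}
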