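#' @include AllClasses.R register.R sphere-fit.R
NULL

#' Locate the femoral head centre by robust sphere fitting
#'
#' Fits the close-fit sphere to the head-region vertices (robust
#' fovea-exclusion passes enabled); the fitted centre is the head-centre
#' landmark.
#'
#' @param model a \linkS4class{FemurModel} with a non-empty head region.
#' @return A list with components \code{sphere} (\linkS4class{Sphere}) and
#'   \code{report} (\linkS4class{SphereFitReport}).
#' @export
locateHeadCenter <- function(model) {
  stopifnot(is(model, "FemurModel"))
  pts <- .regionVertices(model, "head")
  if (nrow(pts) < 4L)
    stop("head region has fewer than 4 vertices; cannot fit the head sphere")
  report <- fitSphere(pts, robust = TRUE)
  list(sphere = report@sphere, report = report)
}

#' Locate the deepest point of the fovea capitis
#'
#' Among head-region vertices, the inward radial deficit relative to the
#' fitted head sphere is r - ||p - c||. The vertex of maximal deficit is
#' returned provided the deficit exceeds \code{threshold} (default 1 mm);
#' exact ties are broken by the lexicographically smallest coordinates.
#'
#' @param model a \linkS4class{FemurModel}.
#' @param sphere the fitted head \linkS4class{Sphere}.
#' @param threshold minimal deficit (mm) for a fovea detection.
#' @return The fovea vertex as a 3-vector (mm); error of class
#'   \code{foveaNotFound} when no vertex exceeds the threshold (supply a
#'   manual landmark in that case).
#' @export
locateFovea <- function(model, sphere, threshold = 1.0) {
  stopifnot(is(model, "FemurModel"), is(sphere, "Sphere"))
  pts <- .regionVertices(model, "head")
  if (!nrow(pts)) stop("head region is empty")
  deficit <- sphere@radius -
    sqrt(rowSums((pts - rep(sphere@center, each = nrow(pts)))^2))
  cand <- which(deficit > threshold)
  if (!length(cand))
    stop(structure(class = c("foveaNotFound", "error", "condition"),
                   list(message = sprintf(
                     "no fovea found: maximal inward deficit %.3f mm does not exceed threshold %.3f mm",
                     max(deficit), threshold), call = sys.call(-1))))
  best <- cand[deficit[cand] == max(deficit[cand])]
  if (length(best) > 1L) {
    p <- pts[best, , drop = FALSE]
    best <- best[order(p[, 1], p[, 2], p[, 3])[1L]]
  }
  as.numeric(pts[best, ])
}

.fittedLandmarks <- function(model, foveaThreshold = 1.0) {
  hc <- locateHeadCenter(model)
  fv <- locateFovea(model, hc$sphere, threshold = foveaThreshold)
  list(landmarks = LandmarkSet(list(head_center = hc$sphere@center,
                                    fovea_deepest = fv),
                               source = "fitted", side = model@side),
       report = hc$report)
}

#' Measure the 3D displacement of an undisplaced femoral neck fracture
#'
#' The full measurement protocol for one patient: (1) the fractured-side
#' model is mirrored across the sagittal plane; (2) the mirrored model is
#' rigidly superimposed onto the healthy contralateral model by ICP anchored
#' on the neck and shaft; (3) the femoral head centre (robust close-fit
#' sphere) and the deepest fovea point are located on both models — manual
#' landmarks, when given, take precedence and fractured-side manual picks
#' (expressed in the original, unmirrored frame) are carried through the same
#' mirror + registration map; (4) the displacement triple is computed:
#' d1 = distance between head centres, d2 = distance between fovea points,
#' alpha = angle between the centre-to-fovea lines.
#'
#' @param fractured,healthy \linkS4class{FemurModel}s of opposite sides
#'   (override with \code{allowSameSide}).
#' @param manualLandmarks optional list with elements \code{fractured} and/or
#'   \code{healthy}, each a \linkS4class{LandmarkSet} containing
#'   \code{head_center} and \code{fovea_deepest}.
#' @param plane mirror plane (\code{\link{mirrorPlane}}); default x = 0.
#' @param regions regions anchoring the registration; default neck + shaft.
#' @param foveaThreshold fovea detection threshold (mm), see
#'   \code{\link{locateFovea}}.
#' @param allowSameSide skip the opposite-sides check.
#' @param ... further arguments passed to \code{\link{registerRigid}}.
#' @return A \linkS4class{DisplacementResult}.
#' @export
measureDisplacement <- function(fractured, healthy, manualLandmarks = NULL,
                                plane = mirrorPlane(),
                                regions = c("neck", "shaft"),
                                foveaThreshold = 1.0,
                                allowSameSide = FALSE, ...) {
  stopifnot(is(fractured, "FemurModel"), is(healthy, "FemurModel"))
  if (!allowSameSide && fractured@side == healthy@side)
    stop("fractured and healthy models must be opposite sides ",
         "(set allowSameSide = TRUE to override)")
  mirrored <- mirrorMesh(fractured, plane)
  reg <- registerRigid(mirrored, healthy, regions = regions, ...)
  aligned <- applyTransform(reg@transform, mirrored)

  emptyFit <- list()
  manH <- manualLandmarks$healthy
  manF <- manualLandmarks$fractured
  need <- function(lms, nm) {
    p <- lms@points[[nm]]
    if (is.null(p)) stop("manual landmark set is missing '", nm, "'")
    p
  }

  if (is.null(manH)) {
    lh <- .fittedLandmarks(healthy, foveaThreshold)
    lmsH <- lh$landmarks; fitH <- lh$report
  } else {
    lmsH <- LandmarkSet(list(head_center = need(manH, "head_center"),
                             fovea_deepest = need(manH, "fovea_deepest")),
                        source = "manual", side = healthy@side)
    fitH <- NULL
  }
  if (is.null(manF)) {
    lf <- .fittedLandmarks(aligned, foveaThreshold)
    lmsF <- lf$landmarks; fitF <- lf$report
  } else {
    # manual fractured picks live in the original frame: mirror then register
    mapPoint <- function(p)
      applyTransform(reg@transform, .reflectPoints(p, mirrorPlane(plane$point, plane$normal))[1, ])
    lmsF <- LandmarkSet(list(head_center = mapPoint(need(manF, "head_center")),
                             fovea_deepest = mapPoint(need(manF, "fovea_deepest"))),
                        source = "manual", side = aligned@side)
    fitF <- NULL
  }

  cH <- lmsH@points$head_center; fH <- lmsH@points$fovea_deepest
  cF <- lmsF@points$head_center; fF <- lmsF@points$fovea_deepest
  new("DisplacementResult",
      d1 = pointDistance(cF, cH),
      d2 = pointDistance(fF, fH),
      alpha = angleBetweenLines(cF, fF, cH, fH),
      landmarksHealthy = lmsH,
      landmarksFracturedMirrored = lmsF,
      registration = reg,
      sphereFits = Filter(Negate(is.null), list(healthy = fitH,
                                                fractured = fitF)))
}

#' Summarise displacement results per group
#'
#' Per-group descriptives of d1, d2 and alpha plus the clinically reported
#' threshold fractions: displacement of the head centre exceeding 10 mm
#' (strict), rotational displacement within 10-50 degrees (inclusive bounds)
#' and rotation exceeding 20 degrees (strict).
#'
#' @param results list of \linkS4class{DisplacementResult}s.
#' @param groups vector of group labels, one per result (default: one group).
#' @return A data.frame with one row per group: n, mean/sd of d1, d2, alpha,
#'   \code{frac_d1_gt_10mm}, \code{frac_alpha_10_50}, \code{frac_alpha_gt_20}.
#' @export
summarizeCohort <- function(results, groups = rep("all", length(results))) {
  if (!length(results)) stop("summarizeCohort: no results")
  if (length(groups) != length(results))
    stop("summarizeCohort: one group label per result is required")
  stopifnot(all(vapply(results, is, logical(1), "DisplacementResult")))
  .summarizeValues(vapply(results, d1, numeric(1)),
                   vapply(results, d2, numeric(1)),
                   vapply(results, alpha3d, numeric(1)),
                   groups)
}

# Group descriptives + threshold fractions on raw d1/d2/alpha vectors.
.summarizeValues <- function(d1v, d2v, av, groups) {
  out <- lapply(split(seq_along(d1v), factor(groups)), function(i) {
    sdOr0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
    data.frame(n = length(i),
               d1_mean = mean(d1v[i]), d1_sd = sdOr0(d1v[i]),
               d2_mean = mean(d2v[i]), d2_sd = sdOr0(d2v[i]),
               alpha_mean = mean(av[i]), alpha_sd = sdOr0(av[i]),
               frac_d1_gt_10mm = mean(d1v[i] > 10),
               frac_alpha_10_50 = mean(av[i] >= 10 & av[i] <= 50),
               frac_alpha_gt_20 = mean(av[i] > 20))
  })
  res <- do.call(rbind, out)
  res <- cbind(group = names(out), res)
  rownames(res) <- NULL
  res
}

#' Write displacement results as CSV and JSON reports
#'
#' The CSV has one row per case (case id, group, d1_mm, d2_mm, alpha_deg,
#' registration RMS, the two sphere-fit RMS residuals, landmark source); the
#' JSON carries the full nested reports.
#'
#' @param results list of \linkS4class{DisplacementResult}s.
#' @param caseIds,groups vectors parallel to \code{results}.
#' @param csvPath,jsonPath output paths (NULL to skip either).
#' @return Invisibly, the CSV data.frame.
#' @export
writeDisplacementReport <- function(results,
                                    caseIds = seq_along(results),
                                    groups = rep("all", length(results)),
                                    csvPath = NULL, jsonPath = NULL) {
  stopifnot(all(vapply(results, is, logical(1), "DisplacementResult")))
  rmsOf <- function(r, which) {
    f <- r@sphereFits[[which]]
    if (is.null(f)) NA_real_ else f@rmsResidual
  }
  df <- data.frame(
    case_id = caseIds,
    group = groups,
    d1_mm = vapply(results, d1, numeric(1)),
    d2_mm = vapply(results, d2, numeric(1)),
    alpha_deg = vapply(results, alpha3d, numeric(1)),
    registration_rms_mm = vapply(results, function(r) r@registration@rmsError,
                                 numeric(1)),
    sphere_rms_healthy_mm = vapply(results, rmsOf, numeric(1), "healthy"),
    sphere_rms_fractured_mm = vapply(results, rmsOf, numeric(1), "fractured"),
    landmark_source = vapply(results, function(r)
      paste(r@landmarksHealthy@source, r@landmarksFracturedMirrored@source,
            sep = "/"), character(1)))
  if (!is.null(csvPath)) utils::write.csv(df, csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    full <- lapply(seq_along(results), function(i) {
      r <- results[[i]]
      list(case_id = caseIds[i], group = groups[i],
           d1_mm = r@d1, d2_mm = r@d2, alpha_deg = r@alpha,
           landmarks_healthy = r@landmarksHealthy@points,
           landmarks_fractured_mirrored = r@landmarksFracturedMirrored@points,
           landmark_source = c(r@landmarksHealthy@source,
                               r@landmarksFracturedMirrored@source),
           registration = list(rms_mm = r@registration@rmsError,
                               iterations = r@registration@iterations,
                               converged = r@registration@converged,
                               rotation = r@registration@transform@rotation,
                               translation = r@registration@transform@translation))
    })
    jsonlite::write_json(full, jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}
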