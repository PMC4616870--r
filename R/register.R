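#' @include AllClasses.R transforms.R
NULL

# Least-squares rigid transform (Kabsch/Umeyama, no scale) mapping the rows
# of src onto the rows of dst, optionally weighted by keep (logical).
.kabsch <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  sv <- svd(H)
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  RigidTransform(R, cd - as.numeric(R %*% cs))
}

.nnQuery <- function(query, ref) .nnBrute(query, ref)

# Deterministic even subsample of at most k rows.
.evenSample <- function(n, k) {
  if (n <= k) seq_len(n)
  else unique(round(seq(1L, n, length.out = k)))
}

.regionVertices <- function(model, regions) {
  codes <- .REGION_CODES[regions]
  if (any(is.na(codes))) stop("unknown region name in ", deparse(regions))
  model@mesh@vertices[model@regionMask %in% codes, , drop = FALSE]
}

# Candidate principal-axes initializations: align source PCA axes to target
# PCA axes under the 4 proper sign combinations.
.pcaInits <- function(src, dst) {
  es <- eigen(cov(src), symmetric = TRUE)$vectors
  ed <- eigen(cov(dst), symmetric = TRUE)$vectors
  if (det(es) < 0) es[, 3] <- -es[, 3]
  if (det(ed) < 0) ed[, 3] <- -ed[, 3]
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  cs <- colMeans(src); cd <- colMeans(dst)
  lapply(signs, function(s) {
    R <- ed %*% diag(s) %*% t(es)
    RigidTransform(R, cd - as.numeric(R %*% cs))
  })
}

#' Rigid superimposition by iterative closest point
#'
#' Registers \code{source} onto \code{target} with nearest-vertex ICP
#' restricted to the requested anatomical regions. The default anchors the
#' alignment on the shaft and neck and deliberately excludes the head: the
#' displaced head fragment must not drive the superimposition that the
#' displacement is measured against. Initialisation is centroid +
#' principal-axes alignment; among the four proper sign choices the one with
#' the smallest RMS after one correspondence pass wins, ties going to the
#' rotation closest to the identity. Iteration stops when the RMS change
#' falls below \code{tol} or after \code{maxIter} iterations.
#'
#' @param source,target \linkS4class{FemurModel}s (the source is typically
#'   the mirrored fractured side).
#' @param regions character vector of region names used for correspondence;
#'   default \code{c("neck", "shaft")}.
#' @param trim fraction of best correspondences kept when re-estimating the
#'   transform (1 = plain ICP; down to 0.8 to resist fracture-gap outliers).
#' @param maxIter iteration cap (default 200).
#' @param tol RMS-change convergence tolerance in mm (default 1e-6).
#' @param maxSourcePoints deterministic even subsample size of the source
#'   cloud (speed knob; correspondence still searches the full target cloud).
#' @param sanityRms RMS (mm) above which the result is flagged with a warning
#'   and \code{converged = FALSE}.
#' @return A \linkS4class{RegistrationReport} whose transform maps source
#'   coordinates into the target frame.
#' @export
registerRigid <- function(source, target, regions = c("neck", "shaft"),
                          trim = 1.0, maxIter = 200L, tol = 1e-6,
                          maxSourcePoints = 1500L, sanityRms = 5) {
  stopifnot(is(source, "FemurModel"), is(target, "FemurModel"))
  if (!length(regions)) stop("registerRigid: empty region selection")
  if (trim < 0.8 || trim > 1) stop("trim must lie in [0.8, 1]")
  srcAll <- .regionVertices(source, regions)
  dst <- .regionVertices(target, regions)
  if (nrow(srcAll) < 3L || nrow(dst) < 3L)
    stop("registerRigid: selected regions are empty or too small")
  src <- srcAll[.evenSample(nrow(srcAll), maxSourcePoints), , drop = FALSE]

  scoreInit <- function(tf) {
    q <- applyTransform(tf, src)
    sqrt(mean(.nnQuery(q, dst)$dist2))
  }
  inits <- .pcaInits(src, dst)
  scores <- vapply(inits, scoreInit, numeric(1))
  best <- which(scores <= min(scores) + 1e-9)
  if (length(best) > 1L) {  # tie-break: rotation closest to identity
    angs <- vapply(inits[best], function(tf) rotationAngle(tf@rotation),
                   numeric(1))
    best <- best[which.min(angs)]
  } else best <- best[1L]
  tf <- inits[[best]]

  rms <- Inf; iter <- 0L; converged <- FALSE
  nKeep <- max(3L, floor(trim * nrow(src)))
  for (it in seq_len(maxIter)) {
    iter <- it
    q <- applyTransform(tf, src)
    nn <- .nnQuery(q, dst)
    ord <- if (nKeep < nrow(src)) order(nn$dist2)[seq_len(nKeep)]
           else seq_len(nrow(src))
    tf <- .kabsch(src[ord, , drop = FALSE],
                  dst[nn$index[ord], , drop = FALSE])
    q <- applyTransform(tf, src)
    nn <- .nnQuery(q, dst)
    newRms <- sqrt(mean(nn$dist2))
    if (is.finite(rms) && abs(rms - newRms) < tol) {
      rms <- newRms; converged <- TRUE; break
    }
    rms <- newRms
  }
  if (rms > sanityRms) {
    warning(sprintf("registration RMS %.3f mm exceeds sanity bound %.3f mm",
                    rms, sanityRms))
    converged <- FALSE
  }
  new("RegistrationReport", transform = tf, rmsError = rms,
      iterations = iter, converged = converged)
}
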