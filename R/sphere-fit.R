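#' @include AllClasses.R
NULL

# Algebraic (Coope-style) linear sphere fit: ||p||^2 = 2 p.c + (r^2 - ||c||^2)
.sphereFitAlgebraic <- function(p) {
  A <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  qrA <- qr(A)
  if (qrA$rank < 4L)
    stop("degenerate geometry: points are coplanar or otherwise rank-deficient")
  d <- svd(A, nu = 0, nv = 0)$d
  if (d[1] / d[4] > 1e8)
    stop("degenerate geometry: near-coplanar points (condition number above threshold)")
  x <- qr.coef(qrA, b)
  ctr <- x[1:3]
  r2 <- x[4] + sum(ctr^2)
  if (r2 <= 0) stop("degenerate geometry: non-positive fitted radius")
  list(center = as.numeric(ctr), radius = sqrt(r2))
}

# Gauss-Newton refinement of sum((||p-c|| - r)^2); never returns a worse
# RMS than its starting point.
.sphereFitGeometric <- function(p, init, maxIter = 100L, tol = 1e-12) {
  theta <- c(init$center, init$radius)
  rmsOf <- function(th) {
    d <- sqrt(rowSums((p - rep(th[1:3], each = nrow(p)))^2))
    sqrt(mean((d - th[4])^2))
  }
  best <- theta; bestRms <- rmsOf(theta); iter <- 0L
  lambda <- 0
  for (it in seq_len(maxIter)) {
    iter <- it
    diffs <- p - rep(theta[1:3], each = nrow(p))
    d <- sqrt(rowSums(diffs^2))
    d[d < 1e-12] <- 1e-12
    res <- d - theta[4]
    J <- cbind(-diffs / d, -1)
    step <- tryCatch(
      solve(crossprod(J) + lambda * diag(4), -crossprod(J, res)),
      error = function(e) NULL)
    if (is.null(step)) break
    cand <- theta + as.numeric(step)
    candRms <- rmsOf(cand)
    if (candRms <= bestRms + 1e-15) {
      moved <- max(abs(cand - theta))
      theta <- cand
      if (candRms < bestRms) { best <- cand; bestRms <- candRms }
      lambda <- lambda / 10
      if (moved < tol) break
    } else {
      lambda <- max(lambda * 10, 1e-8)
      if (lambda > 1e8) break
    }
  }
  list(center = best[1:3], radius = best[4], rms = bestRms, iterations = iter)
}

#' Least-squares sphere fit ("close-fit sphere")
#'
#' Fits the sphere minimising the sum of squared radial residuals
#' sum((||p - c|| - r)^2). An algebraic linear fit provides the initial
#' estimate, refined by damped Gauss-Newton iteration on the geometric
#' residuals. With \code{robust = TRUE}, points whose inward radial deficit
#' r - ||p - c|| exceeds \code{excludeThreshold} (the fovea pit, by default
#' anything deeper than 0.5 mm) are dropped and the fit repeated, up to 5
#' passes or until the exclusion set stabilises — this keeps the fovea from
#' biasing the femoral-head sphere.
#'
#' @param points n x 3 matrix of points (mm), n >= 4, non-coplanar.
#' @param robust logical; run the fovea-exclusion passes.
#' @param excludeThreshold inward deficit (mm) beyond which a point is
#'   excluded in robust mode.
#' @return A \linkS4class{SphereFitReport}.
#' @examples
#' u <- matrix(rnorm(300), ncol = 3)
#' u <- u / sqrt(rowSums(u^2))
#' fit <- fitSphere(sweep(10 * u, 2, c(1, 2, 3), "+"))
#' center(fit@sphere)  # ~ (1, 2, 3)
#' @export
fitSphere <- function(points, robust = FALSE, excludeThreshold = 0.5) {
  p <- .asPoints(points)
  if (!all(is.finite(p))) stop("fitSphere: points must be finite")
  if (nrow(p) < 4L) stop("fitSphere: at least 4 points are required")
  keep <- rep(TRUE, nrow(p))
  fit <- NULL
  passes <- if (robust) 5L else 1L
  for (pass in seq_len(passes)) {
    init <- .sphereFitAlgebraic(p[keep, , drop = FALSE])
    fit <- .sphereFitGeometric(p[keep, , drop = FALSE], init)
    if (!robust) break
    d <- sqrt(rowSums((p - rep(fit$center, each = nrow(p)))^2))
    newKeep <- (fit$radius - d) <= excludeThreshold
    if (sum(newKeep) < 4L || identical(newKeep, keep)) break
    keep <- newKeep
  }
  new("SphereFitReport",
      sphere = Sphere(fit$center, fit$radius),
      rmsResidual = fit$rms,
      nPointsUsed = sum(keep),
      nExcluded = sum(!keep),
      iterations = as.integer(fit$iterations))
}
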