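#' @include AllClasses.R
NULL

#' Landis-Koch verbal interpretation of a kappa coefficient
#'
#' Bands: below 0 "none"; 0-0.2 "slight"; 0.21-0.4 "fair"; 0.41-0.6
#' "moderate"; 0.61-0.8 "substantial"; 0.81-1.0 "almost perfect". Band
#' boundaries belong to the lower band (0.2 is "slight", 0.4 "fair", 0.6
#' "moderate", 0.8 "substantial").
#'
#' @param kappa numeric in [-1, 1].
#' @return Character label.
#' @examples
#' landisKochCategory(0.937)  # "almost perfect"
#' landisKochCategory(0.5)    # "moderate"
#' @export
landisKochCategory <- function(kappa) {
  if (length(kappa) != 1L || !is.finite(kappa) ||
      kappa < -1 - 1e-12 || kappa > 1 + 1e-12)
    stop("kappa must be a single value in [-1, 1]")
  if (kappa < 0) "none"
  else if (kappa <= 0.2) "slight"
  else if (kappa <= 0.4) "fair"
  else if (kappa <= 0.6) "moderate"
  else if (kappa <= 0.8) "substantial"
  else "almost perfect"
}

.checkRatingMatrix <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (any(is.na(ratings))) stop("rating table must have no missing cells")
  if (nrow(ratings) < 2L) stop("at least 2 subjects are required")
  if (ncol(ratings) < 2L) stop("at least 2 raters are required")
  ratings
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement for m >= 2 raters assigning one categorical
#' rating per subject: kappa = (Pbar - Pe) / (1 - Pe), with Pbar the mean
#' observed pairwise agreement per subject and Pe the chance agreement from
#' the pooled category proportions.
#'
#' @param ratings subjects x raters matrix (or data.frame) of categorical
#'   ratings (any atomic type); no missing cells.
#' @return An \linkS4class{AgreementResult} with the Landis-Koch label.
#' @export
fleissKappa <- function(ratings) {
  ratings <- .checkRatingMatrix(ratings)
  n <- nrow(ratings); m <- ncol(ratings)
  cats <- sort(unique(as.vector(ratings)))
  counts <- vapply(cats, function(k) rowSums(ratings == k),
                   numeric(n))
  counts <- matrix(counts, nrow = n)
  Pi <- (rowSums(counts^2) - m) / (m * (m - 1))
  Pbar <- mean(Pi)
  pj <- colSums(counts) / (n * m)
  Pe <- sum(pj^2)
  if (abs(1 - Pe) < 1e-12)
    stop("undefined kappa: chance agreement Pe = 1 (a single category used throughout)")
  kap <- (Pbar - Pe) / (1 - Pe)
  new("AgreementResult", kappa = kap, method = "fleiss",
      weightScheme = "none", category = landisKochCategory(kap))
}

#' Cohen's weighted kappa for two raters over ordered categories
#'
#' Weighted disagreement kappa = 1 - sum(w * O) / sum(w * E) with linear
#' (|i - j| / (k - 1)) or quadratic ((i - j)^2 / (k - 1)^2) disagreement
#' weights; O the observed and E the chance-expected cross-classification.
#' For two categories the schemes coincide.
#'
#' @param ratingsA,ratingsB equal-length rating vectors.
#' @param categories the ordered category set; defaults to the sorted values
#'   observed in either vector.
#' @param scheme "linear" or "quadratic".
#' @return An \linkS4class{AgreementResult}.
#' @export
weightedKappa <- function(ratingsA, ratingsB, categories = NULL,
                          scheme = c("linear", "quadratic")) {
  scheme <- match.arg(scheme)
  if (length(ratingsA) != length(ratingsB))
    stop("rating vectors must have equal length")
  if (!length(ratingsA)) stop("rating vectors must be non-empty")
  if (is.null(categories))
    categories <- sort(unique(c(ratingsA, ratingsB)))
  fa <- factor(ratingsA, levels = categories)
  fb <- factor(ratingsB, levels = categories)
  if (any(is.na(fa)) || any(is.na(fb)))
    stop("ratings outside the declared category set")
  k <- length(categories)
  O <- table(fa, fb) / length(ratingsA)
  E <- outer(table(fa) / length(fa), table(fb) / length(fb))
  ij <- abs(outer(seq_len(k), seq_len(k), "-"))
  W <- if (k == 1L) matrix(0, 1, 1)
       else if (scheme == "linear") ij / (k - 1) else (ij / (k - 1))^2
  denom <- sum(W * E)
  if (denom < 1e-12)
    stop("undefined kappa: chance-agreement denominator is zero")
  kap <- 1 - sum(W * O) / denom
  new("AgreementResult", kappa = kap, method = "cohen_weighted",
      weightScheme = scheme, category = landisKochCategory(kap))
}

#' Discretize repeated landmark picks into agreement categories
#'
#' The reviewer study records continuous 3D landmark picks; kappa needs
#' categories. Each rater's pick for a subject is labelled "agree" when it
#' lies within \code{tolerance} mm of the subject's consensus location (the
#' coordinate-wise median over raters), else "disagree".
#'
#' @param picks a subjects-list of rater-lists of 3-vectors (mm), or a
#'   3-dimensional array [subject, rater, coordinate].
#' @param tolerance agreement radius in mm (default 2).
#' @return A subjects x raters character matrix suitable for
#'   \code{\link{fleissKappa}}.
#' @export
discretizePicks <- function(picks, tolerance = 2) {
  if (is.array(picks) && length(dim(picks)) == 3L) {
    picks <- lapply(seq_len(dim(picks)[1]), function(i)
      lapply(seq_len(dim(picks)[2]), function(j) picks[i, j, ]))
  }
  if (tolerance <= 0) stop("tolerance must be > 0")
  out <- t(vapply(picks, function(subj) {
    P <- do.call(rbind, lapply(subj, as.numeric))
    consensus <- apply(P, 2, stats::median)
    d <- sqrt(rowSums((P - rep(consensus, each = nrow(P)))^2))
    ifelse(d <= tolerance, "agree", "disagree")
  }, character(length(picks[[1]]))))
  out
}
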