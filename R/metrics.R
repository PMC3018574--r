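# Resolution matrix, PSF/CTF extraction and the three per-source metrics:
# dipole localization error (DLE), spatial dispersion (SD) and overall
# amplitude (OA).

#' Resolution matrix R = G L
#'
#' Computed column-by-column through the same matrix-vector product used by
#' \code{\link{applyInverse}}, so each column of R is bit-identical to the
#' inverse operator applied to the corresponding leadfield column (the PSF
#' of that source).
#'
#' @param op an \code{InverseOperator}.
#' @param leadfield the \code{Leadfield} it was built from.
#' @return a \code{\linkS4class{ResolutionMatrix}}.
#' @export
resolutionMatrix <- function(op, leadfield) {
  stopifnot(is(op, "InverseOperator"), is(leadfield, "Leadfield"))
  G <- getMatrix(op)
  L <- getMatrix(leadfield)
  if (ncol(G) != nrow(L)) stop("operator/leadfield shape mismatch")
  R <- vapply(seq_len(ncol(L)),
              function(j) as.numeric(G %*% matrix(L[, j], ncol = 1)),
              numeric(nrow(G)))
  new("ResolutionMatrix", matrix = R, method = methodTag(op),
      sourceRef = leadfield@sourceRef)
}

#' Point-spread function of source i
#'
#' Column i of the resolution matrix: how a unit point source at i is
#' represented in the estimate.
#'
#' @param resmat a \code{ResolutionMatrix}.
#' @param i source index.
#' @return numeric vector over sources.
#' @export
psf <- function(resmat, i) {
  stopifnot(is(resmat, "ResolutionMatrix"))
  if (i < 1 || i > ncol(resmat@matrix)) stop("source index out of range")
  resmat@matrix[, i]
}

#' Cross-talk function of source i
#'
#' Row i of the resolution matrix: how sources everywhere leak into the
#' estimate at i. Row normalization (dSPM/sLORETA) rescales but never
#' reshapes CTFs.
#'
#' @inheritParams psf
#' @return numeric vector over sources.
#' @export
ctf <- function(resmat, i) {
  stopifnot(is(resmat, "ResolutionMatrix"))
  if (i < 1 || i > nrow(resmat@matrix)) stop("source index out of range")
  resmat@matrix[i, ]
}

#' Dipole localization error of one distribution
#'
#' Euclidean distance (cm) between the location of the peak of
#' \code{|distribution|} and the true source position. Ties at the peak are
#' broken toward the lowest index (and reported via \code{message}).
#'
#' @param distribution numeric vector over sources (a PSF or CTF).
#' @param trueIndex index of the true source.
#' @param sourceSpace the \code{SourceSpace}.
#' @return scalar DLE in centimeters.
#' @export
localizationError <- function(distribution, trueIndex, sourceSpace) {
  stopifnot(is(sourceSpace, "SourceSpace"))
  a <- abs(distribution)
  if (all(a == 0)) stop("all-zero distribution has no peak")
  m <- max(a)
  if (sum(a == m) > 1L)
    message("tied peak amplitudes; taking the lowest index")
  p <- which.max(a)
  100 * sqrt(sum((sourceSpace@positions[p, ] -
                  sourceSpace@positions[trueIndex, ])^2))
}

#' Spatial dispersion of one distribution
#'
#' \deqn{SD_i = \sqrt{\sum_j d_{ij} F_j^2 / \sum_j F_j^2}} with
#' \eqn{d_{ij}} the Euclidean distance (cm) between source j and the true
#' source i; units are square-root-of-centimeters. The amplitude exponent
#' (2 by default) is exposed for sensitivity analyses.
#'
#' @inheritParams localizationError
#' @param exponent exponent applied to \code{|distribution|} in the weights
#'   (1 or 2; default 2).
#' @return scalar SD in sqrt-cm.
#' @export
spatialDispersion <- function(distribution, trueIndex, sourceSpace,
                              exponent = 2) {
  stopifnot(is(sourceSpace, "SourceSpace"))
  w <- abs(distribution)^exponent
  tot <- sum(w)
  if (tot == 0) stop("all-zero distribution has no dispersion")
  d <- 100 * sqrt(colSums((t(sourceSpace@positions) -
                           sourceSpace@positions[trueIndex, ])^2))
  sqrt(sum(d * w) / tot)
}

#' Overall amplitude of one distribution
#'
#' Sum of absolute amplitudes, \eqn{A_i = \sum_j |F_j|} (unnormalized;
#' \code{\link{metricMaps}} normalizes the map to its per-subject maximum).
#'
#' @param distribution numeric vector over sources.
#' @return scalar amplitude.
#' @export
overallAmplitude <- function(distribution) sum(abs(distribution))

#' Metric maps for all PSFs or CTFs
#'
#' Evaluates DLE, SD and OA for every column (PSF mode) or row (CTF mode)
#' of the resolution matrix, then normalizes the OA map to its maximum
#' (per subject), so relative amplitudes remain comparable across subjects.
#'
#' @param resmat a \code{ResolutionMatrix} matching \code{sourceSpace}.
#' @param mode \code{"PSF"} or \code{"CTF"}.
#' @param sourceSpace the \code{SourceSpace}.
#' @param subjectId identifier stored in the result.
#' @param sdExponent amplitude exponent for SD (default 2).
#' @return a \code{\linkS4class{MetricMaps}}.
#' @export
metricMaps <- function(resmat, mode = c("PSF", "CTF"), sourceSpace,
                       subjectId = "template", sdExponent = 2) {
  stopifnot(is(resmat, "ResolutionMatrix"), is(sourceSpace, "SourceSpace"))
  mode <- match.arg(mode)
  R <- resmat@matrix
  n <- nSources(sourceSpace)
  if (nrow(R) != n) stop("resolution matrix does not match the source space")
  FF <- if (mode == "PSF") R else t(R)       # column i = distribution for source i
  A <- abs(FF)
  if (any(colSums(A) == 0))
    stop("all-zero distribution at source index ", which(colSums(A) == 0)[1])
  D <- sourceDistances(sourceSpace, units = "cm")
  peaks <- vapply(seq_len(n), function(i) which.max(A[, i]), integer(1))
  dleV <- D[cbind(peaks, seq_len(n))]
  W <- A^sdExponent
  sdV <- sqrt(colSums(D * W) / colSums(W))
  oaV <- colSums(A)
  oaV <- oaV / max(oaV)
  new("MetricMaps", mode = mode, method = resmat@method,
      subjectId = subjectId, dle = dleV, sd = sdV, oa = oaV)
}
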