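# Minimum-norm inverse operator and its dSPM / sLORETA row-normalized
# variants.

#' Regularization parameter from a target SNR
#'
#' Returns \eqn{\lambda = \mathrm{tr}(L L^T) / (\mathrm{tr}(C)\,
#' \mathrm{snr}^2)}: the scaled noise covariance \eqn{\lambda C} then has
#' average sensor power \eqn{1/\mathrm{snr}^2} of the average signal power,
#' a whitening-free transcription of the usual \eqn{\lambda \propto
#' 1/\mathrm{SNR}^2} convention. The study default is \code{snr = 3}.
#'
#' @param leadfield a \code{Leadfield}.
#' @param noise a \code{NoiseCovariance}.
#' @param snr assumed amplitude signal-to-noise ratio (> 0).
#' @return scalar lambda >= 0.
#' @export
regularizationLambda <- function(leadfield, noise, snr = 3) {
  stopifnot(is(leadfield, "Leadfield"), is(noise, "NoiseCovariance"))
  .assertScalarNum(snr, "snr", positive = TRUE)
  trC <- sum(diag(getMatrix(noise)))
  if (trC <= 0) stop("noise covariance has non-positive trace")
  sum(getMatrix(leadfield)^2) / (trC * snr^2)
}

# Cholesky factor of L L^T + lambda C, with one round of diagonal loading
# (1e-10 x mean diagonal) if the factorization fails. Returns list(U, kappa).
.regularizedChol <- function(L, C, lambda) {
  M <- tcrossprod(L) + lambda * C
  U <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(U)) {
    load <- 1e-10 * mean(diag(M))
    message(sprintf(
      "LL' + lambda*C not positive definite; applying diagonal loading %.3g", load))
    M <- M + diag(load, nrow(M))
    U <- tryCatch(chol(M), error = function(e)
      stop(sprintf("singular system: condition number ~ %.3g", kappa(M))))
  }
  d <- diag(U)^2
  list(U = U, kappa = max(d) / min(d))
}

#' Classical minimum-norm (MNE) inverse operator
#'
#' Computes \eqn{G = L^T (L L^T + \lambda C)^{-1}} via a Cholesky
#' factorization of the regularized Gram matrix. Weights are all ones;
#' pass the result to \code{\link{dspmWeights}} / \code{\link{sloretaWeights}}
#' and \code{\link{applyNormalization}} for the noise-normalized variants.
#'
#' @param leadfield a \code{Leadfield}.
#' @param noise a \code{NoiseCovariance}.
#' @param lambda regularization parameter; defaults to
#'   \code{regularizationLambda(leadfield, noise, snr)}.
#' @param snr SNR used when \code{lambda} is derived (default 3).
#' @return an \code{\linkS4class{InverseOperator}} with method "MNE".
#' @export
mneOperator <- function(leadfield, noise, lambda = NULL, snr = 3) {
  stopifnot(is(leadfield, "Leadfield"), is(noise, "NoiseCovariance"))
  L <- getMatrix(leadfield)
  C <- getMatrix(noise)
  if (nrow(L) != nrow(C)) stop("leadfield and covariance channel counts differ")
  if (is.null(lambda)) lambda <- regularizationLambda(leadfield, noise, snr)
  if (lambda < 0) stop("'lambda' must be >= 0")
  f <- .regularizedChol(L, C, lambda)
  message(sprintf("MNE operator: condition number of LL' + lambda*C ~ %.3g", f$kappa))
  G <- t(backsolve(f$U, forwardsolve(t(f$U), L)))
  new("InverseOperator", matrix = G, method = "MNE", lambda = lambda,
      snr = snr, weights = rep(1, nrow(G)), noiseRef = noise@id)
}

#' dSPM normalization weights
#'
#' Per-source weights \eqn{w_i = 1 / \sqrt{[G (C / n_{av}) G^T]_{ii}}}: the
#' inverse of the minimum-norm estimate of the noise standard deviation at
#' each source, with the covariance scaled by the number of averaged trials
#' stored in the \code{NoiseCovariance} (study default 100).
#'
#' @param mneOp an MNE \code{InverseOperator}.
#' @param noise the \code{NoiseCovariance}.
#' @return numeric vector of strictly positive weights.
#' @export
dspmWeights <- function(mneOp, noise) {
  stopifnot(is(mneOp, "InverseOperator"), is(noise, "NoiseCovariance"))
  if (methodTag(mneOp) != "MNE") stop("dSPM weights must be derived from an MNE operator")
  G <- getMatrix(mneOp)
  C <- getMatrix(noise) / noise@nAverages
  v <- rowSums((G %*% C) * G)
  if (any(v <= 0))
    stop("zero noise projection at source index ", which(v <= 0)[1])
  1 / sqrt(v)
}

#' sLORETA normalization weights
#'
#' Per-source weights \eqn{w_i = 1 / \sqrt{[G L]_{ii}}}, the inverse square
#' root of the diagonal of the MNE resolution matrix. The diagonal is
#' strictly positive whenever the regularized Gram matrix is positive
#' definite and no leadfield column is zero; this normalization guarantees
#' zero dipole localization error of the PSFs.
#'
#' @param mneOp an MNE \code{InverseOperator}.
#' @param leadfield the \code{Leadfield}.
#' @return numeric vector of strictly positive weights.
#' @export
sloretaWeights <- function(mneOp, leadfield) {
  stopifnot(is(mneOp, "InverseOperator"), is(leadfield, "Leadfield"))
  if (methodTag(mneOp) != "MNE") stop("sLORETA weights must be derived from an MNE operator")
  G <- getMatrix(mneOp)
  L <- getMatrix(leadfield)
  d <- rowSums(G * t(L))      # diag(G L)
  if (any(d <= 0))
    stop("non-positive resolution-matrix diagonal at source index ",
         which(d <= 0)[1])
  1 / sqrt(d)
}

#' Row-normalize an MNE operator
#'
#' Scales row i of the MNE operator by \code{weights[i]} and tags the
#' result (\code{"dSPM"} or \code{"sLORETA"}). Row scaling changes the
#' shapes of PSFs but only the amplitudes of CTFs.
#'
#' @param mneOp an MNE \code{InverseOperator}.
#' @param weights strictly positive finite vector, one per source.
#' @param methodTag \code{"dSPM"} or \code{"sLORETA"}.
#' @return a new \code{InverseOperator}.
#' @export
applyNormalization <- function(mneOp, weights, methodTag) {
  stopifnot(is(mneOp, "InverseOperator"))
  methodTag <- match.arg(methodTag, c("dSPM", "sLORETA"))
  G <- getMatrix(mneOp)
  if (length(weights) != nrow(G)) stop("need one weight per source")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be strictly positive and finite")
  new("InverseOperator", matrix = weights * G, method = methodTag,
      lambda = mneOp@lambda, snr = mneOp@snr, weights = as.numeric(weights),
      noiseRef = mneOp@noiseRef)
}

#' Apply an inverse operator to sensor data
#'
#' Returns the source estimate \eqn{\hat{j} = G d}.
#'
#' @param op an \code{InverseOperator}.
#' @param dataVector numeric vector of length n_channels (or an
#'   n_channels x t matrix of time samples).
#' @return numeric vector (or n_sources x t matrix) of source estimates.
#' @export
applyInverse <- function(op, dataVector) {
  stopifnot(is(op, "InverseOperator"))
  G <- getMatrix(op)
  d <- if (is.matrix(dataVector)) dataVector else matrix(dataVector, ncol = 1)
  if (nrow(d) != ncol(G))
    stop(sprintf("data length %d does not match %d channels", nrow(d), ncol(G)))
  est <- G %*% d
  if (ncol(est) == 1L) as.numeric(est) else est
}
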