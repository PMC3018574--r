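# S4 classes for the resolution-analysis pipeline.

#' SensorArray: MEG helmet geometry
#'
#' Positions, orientations and types of magnetometer and planar-gradiometer
#' channels on a hemispherical helmet, in a head-centered frame (meters).
#' Magnetometers pick up the field component along \code{orientations};
#' planar gradiometers difference that component between two integration
#' points separated by \code{gradBaseline} along \code{axes}.
#'
#' @slot positions numeric matrix [n_channels x 3], channel positions (m).
#' @slot orientations numeric matrix [n_channels x 3], unit pickup directions.
#' @slot axes numeric matrix [n_channels x 3]; for gradiometers the unit
#'   tangential direction of the two-point baseline, zero rows for
#'   magnetometers.
#' @slot types character vector, \code{"mag"} or \code{"grad"} per channel.
#' @slot gradBaseline numeric scalar > 0, gradiometer baseline (m).
#' @slot id character identifier.
#' @exportClass SensorArray
setClass("SensorArray",
  representation(positions = "matrix", orientations = "matrix",
                 axes = "matrix", types = "character",
                 gradBaseline = "numeric", id = "character"))

setValidity("SensorArray", function(object) {
  n <- nrow(object@positions)
  msg <- character()
  if (ncol(object@positions) != 3L) msg <- c(msg, "positions must be n x 3")
  if (!all(dim(object@orientations) == c(n, 3L)))
    msg <- c(msg, "orientations must match positions")
  if (!all(dim(object@axes) == c(n, 3L))) msg <- c(msg, "axes must be n x 3")
  if (length(object@types) != n) msg <- c(msg, "one type per channel")
  if (!all(object@types %in% c("mag", "grad")))
    msg <- c(msg, "types must be 'mag' or 'grad'")
  if (any(abs(.rowNorms(object@orientations) - 1) > 1e-12))
    msg <- c(msg, "orientations must be unit vectors (tol 1e-12)")
  isg <- object@types == "grad"
  if (any(isg) && any(abs(.rowNorms(object@axes[isg, , drop = FALSE]) - 1) > 1e-12))
    msg <- c(msg, "gradiometer axes must be unit vectors")
  if (length(object@gradBaseline) != 1L || object@gradBaseline <= 0)
    msg <- c(msg, "gradBaseline must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' SourceSpace: cortical dipole grid
#'
#' Dipole positions on a radially folded spherical shell (a synthetic
#' stand-in for a cortical surface with gyri and sulci), with surface-normal
#' orientations and per-source depth below the model scalp sphere.
#'
#' @slot positions numeric matrix [n_sources x 3] (m).
#' @slot orientations numeric matrix [n_sources x 3], unit surface normals.
#' @slot depth numeric vector, radial distance below the conductor surface (m).
#' @slot conductorRadius numeric scalar, radius of the conductor sphere (m).
#' @slot templateId character; subject spaces derived from the same template
#'   share this id and are vertex-wise in correspondence.
#' @exportClass SourceSpace
setClass("SourceSpace",
  representation(positions = "matrix", orientations = "matrix",
                 depth = "numeric", conductorRadius = "numeric",
                 templateId = "character"))

setValidity("SourceSpace", function(object) {
  n <- nrow(object@positions)
  msg <- character()
  if (ncol(object@positions) != 3L) msg <- c(msg, "positions must be n x 3")
  if (!all(dim(object@orientations) == c(n, 3L)))
    msg <- c(msg, "orientations must match positions")
  if (length(object@depth) != n) msg <- c(msg, "one depth per source")
  if (any(abs(.rowNorms(object@orientations) - 1) > 1e-12))
    msg <- c(msg, "orientations must be unit vectors (tol 1e-12)")
  r <- .rowNorms(object@positions)
  if (any(r >= object@conductorRadius))
    msg <- c(msg, "all sources must lie strictly inside the conductor sphere")
  if (length(msg)) msg else TRUE
})

#' NoiseCovariance: sensor-noise second moments
#'
#' Sample covariance of baseline sensor noise, symmetric positive
#' semi-definite by construction, with the number of samples it was
#' estimated from and the trial-averaging divisor used for dSPM weighting.
#'
#' @slot matrix numeric [n_channels x n_channels] symmetric PSD matrix.
#' @slot nSamples integer, samples used for the estimate.
#' @slot nAverages integer, number of averaged trials assumed when scaling
#'   the covariance for dSPM noise estimates (default study value: 100).
#' @slot id character identifier.
#' @exportClass NoiseCovariance
setClass("NoiseCovariance",
  representation(matrix = "matrix", nSamples = "integer",
                 nAverages = "integer", id = "character"))

setValidity("NoiseCovariance", function(object) {
  C <- object@matrix
  msg <- character()
  if (nrow(C) != ncol(C)) msg <- c(msg, "matrix must be square")
  if (max(abs(C - t(C))) != 0) msg <- c(msg, "matrix must be exactly symmetric")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * sum(diag(C)))
    msg <- c(msg, "matrix must be positive semi-definite")
  if (object@nAverages < 1L) msg <- c(msg, "nAverages must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Leadfield: forward gain matrix
#'
#' Sensor response per unit dipole moment for every (channel, source) pair:
#' tesla per A*m for magnetometers, tesla/meter per A*m for planar
#' gradiometers. Fixed-orientation model (one column per source, dipole
#' along the surface normal); no depth weighting.
#'
#' @slot matrix numeric [n_channels x n_sources].
#' @slot sensorRef character, id of the SensorArray used.
#' @slot sourceRef character, templateId of the SourceSpace used.
#' @exportClass Leadfield
setClass("Leadfield",
  representation(matrix = "matrix", sensorRef = "character",
                 sourceRef = "character"))

setValidity("Leadfield", function(object) {
  if (!all(is.finite(object@matrix))) "leadfield entries must be finite" else TRUE
})

#' InverseOperator: linear source estimator
#'
#' The matrix G mapping sensor data to source estimates, with its method tag
#' (MNE, dSPM or sLORETA), the regularization parameter and SNR that
#' produced it, and the per-source row-normalization weights (all ones for
#' MNE). dSPM/sLORETA rows are the MNE rows scaled by \code{weights}.
#'
#' @slot matrix numeric [n_sources x n_channels].
#' @slot method character, one of \code{"MNE"}, \code{"dSPM"}, \code{"sLORETA"}.
#' @slot lambda numeric >= 0, regularization parameter.
#' @slot snr numeric > 0, signal-to-noise ratio the lambda was derived from.
#' @slot weights numeric vector of per-source positive weights.
#' @slot noiseRef character, id of the NoiseCovariance used.
#' @exportClass InverseOperator
setClass("InverseOperator",
  representation(matrix = "matrix", method = "character", lambda = "numeric",
                 snr = "numeric", weights = "numeric", noiseRef = "character"))

setValidity("InverseOperator", function(object) {
  msg <- character()
  if (!object@method %in% c("MNE", "dSPM", "sLORETA"))
    msg <- c(msg, "method must be MNE, dSPM or sLORETA")
  if (length(object@weights) != nrow(object@matrix))
    msg <- c(msg, "one weight per source")
  if (any(!is.finite(object@weights)) || any(object@weights <= 0))
    msg <- c(msg, "weights must be strictly positive and finite")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ResolutionMatrix: R = G L
#'
#' Maps true source distributions to estimated ones. Columns are
#' point-spread functions (PSFs), rows are cross-talk functions (CTFs).
#' For MNE, R is symmetric, so PSFs and CTFs coincide.
#'
#' @slot matrix numeric [n_sources x n_sources].
#' @slot method character, operator method tag.
#' @slot sourceRef character, source-space template id.
#' @exportClass ResolutionMatrix
setClass("ResolutionMatrix",
  representation(matrix = "matrix", method = "character",
                 sourceRef = "character"))

setValidity("ResolutionMatrix", function(object) {
  msg <- character()
  if (nrow(object@matrix) != ncol(object@matrix))
    msg <- c(msg, "resolution matrix must be square")
  if (!all(is.finite(object@matrix))) msg <- c(msg, "entries must be finite")
  if (length(msg)) msg else TRUE
})

#' MetricMaps: per-source resolution metrics
#'
#' Dipole localization error (cm), spatial dispersion (sqrt-cm) and overall
#' amplitude (normalized to its per-subject maximum) for every source, for
#' either the PSFs or the CTFs of one inverse method on one subject.
#'
#' @slot mode character, \code{"PSF"} or \code{"CTF"}.
#' @slot method character, inverse method tag.
#' @slot subjectId character.
#' @slot dle numeric vector >= 0, localization error in centimeters.
#' @slot sd numeric vector >= 0, spatial dispersion in sqrt-centimeters.
#' @slot oa numeric vector, overall amplitude normalized so max(oa) == 1.
#' @exportClass MetricMaps
setClass("MetricMaps",
  representation(mode = "character", method = "character",
                 subjectId = "character", dle = "numeric", sd = "numeric",
                 oa = "numeric"))

setValidity("MetricMaps", function(object) {
  msg <- character()
  if (!object@mode %in% c("PSF", "CTF")) msg <- c(msg, "mode must be PSF or CTF")
  n <- length(object@dle)
  if (length(object@sd) != n || length(object@oa) != n)
    msg <- c(msg, "metric vectors must have equal length")
  if (any(object@dle < 0)) msg <- c(msg, "dle must be >= 0")
  if (any(object@sd < 0)) msg <- c(msg, "sd must be >= 0")
  if (n > 0 && max(object@oa) != 1)
    msg <- c(msg, "oa must be normalized so its maximum is exactly 1")
  if (length(msg)) msg else TRUE
})

#' GroupResult: vertex-wise group statistics
#'
#' Grand-averaged difference, across-subject standard deviation, paired
#' t statistic and two-tailed p value per template vertex for one
#' (method A, method B, metric, mode) contrast.
#'
#' @slot meanMap numeric vector, mean paired difference per vertex.
#' @slot sdMap numeric vector >= 0, sample SD (n-1) of the differences.
#' @slot tMap numeric vector, paired t statistic.
#' @slot pMap numeric vector in [0, 1], two-tailed p.
#' @slot degenerate logical vector, TRUE where the difference had zero
#'   variance across subjects (p set by convention, see
#'   \code{\link{pairedTTestMap}}).
#' @slot contrast character of length 4: method A, method B, metric, mode.
#' @slot nSubjects integer.
#' @exportClass GroupResult
setClass("GroupResult",
  representation(meanMap = "numeric", sdMap = "numeric", tMap = "numeric",
                 pMap = "numeric", degenerate = "logical",
                 contrast = "character", nSubjects = "integer"))

setValidity("GroupResult", function(object) {
  msg <- character()
  n <- length(object@meanMap)
  if (length(object@sdMap) != n || length(object@tMap) != n ||
      length(object@pMap) != n || length(object@degenerate) != n)
    msg <- c(msg, "all maps must have equal length")
  if (any(object@sdMap < 0)) msg <- c(msg, "sdMap must be >= 0")
  if (any(object@pMap < 0 | object@pMap > 1)) msg <- c(msg, "pMap must be in [0,1]")
  if (length(object@contrast) != 4L)
    msg <- c(msg, "contrast must be (methodA, methodB, metric, mode)")
  if (object@nSubjects < 2L) msg <- c(msg, "nSubjects must be >= 2")
  if (length(msg)) msg else TRUE
})
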