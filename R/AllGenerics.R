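# Generics, accessors and show methods.

#' @rdname SensorArray-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname SensorArray-class
#' @export
setGeneric("channelPositions", function(x) standardGeneric("channelPositions"))
#' @rdname SensorArray-class
#' @export
setGeneric("channelOrientations", function(x) standardGeneric("channelOrientations"))
#' @rdname SensorArray-class
#' @export
setGeneric("channelTypes", function(x) standardGeneric("channelTypes"))
#' @rdname SourceSpace-class
#' @export
setGeneric("nSources", function(x) standardGeneric("nSources"))
#' @rdname SourceSpace-class
#' @export
setGeneric("sourcePositions", function(x) standardGeneric("sourcePositions"))
#' @rdname SourceSpace-class
#' @export
setGeneric("sourceOrientations", function(x) standardGeneric("sourceOrientations"))
#' @rdname SourceSpace-class
#' @export
setGeneric("sourceDepths", function(x) standardGeneric("sourceDepths"))
#' @rdname SourceSpace-class
#' @export
setGeneric("templateId", function(x) standardGeneric("templateId"))
#' Matrix payload of a pipeline object
#'
#' Returns the numeric matrix inside a \code{NoiseCovariance},
#' \code{Leadfield}, \code{InverseOperator} or \code{ResolutionMatrix}.
#' @param x the object.
#' @return a numeric matrix.
#' @export
setGeneric("getMatrix", function(x) standardGeneric("getMatrix"))
#' @rdname InverseOperator-class
#' @param x an \code{InverseOperator}.
#' @export
setGeneric("methodTag", function(x) standardGeneric("methodTag"))
#' @rdname InverseOperator-class
#' @export
setGeneric("normWeights", function(x) standardGeneric("normWeights"))
#' Per-source metric vector
#'
#' Extract one metric ("dle", "sd" or "oa") from a \code{MetricMaps}.
#' @param x a \code{MetricMaps}.
#' @param metric one of \code{"dle"}, \code{"sd"}, \code{"oa"}.
#' @return numeric vector, one value per source.
#' @export
setGeneric("metricValues", function(x, metric) standardGeneric("metricValues"))

#' @rdname SensorArray-class
setMethod("nChannels", "SensorArray", function(x) nrow(x@positions))
#' @rdname SensorArray-class
setMethod("channelPositions", "SensorArray", function(x) x@positions)
#' @rdname SensorArray-class
setMethod("channelOrientations", "SensorArray", function(x) x@orientations)
#' @rdname SensorArray-class
setMethod("channelTypes", "SensorArray", function(x) x@types)
#' @rdname SourceSpace-class
setMethod("nSources", "SourceSpace", function(x) nrow(x@positions))
#' @rdname SourceSpace-class
setMethod("sourcePositions", "SourceSpace", function(x) x@positions)
#' @rdname SourceSpace-class
setMethod("sourceOrientations", "SourceSpace", function(x) x@orientations)
#' @rdname SourceSpace-class
setMethod("sourceDepths", "SourceSpace", function(x) x@depth)
#' @rdname SourceSpace-class
setMethod("templateId", "SourceSpace", function(x) x@templateId)
#' @rdname getMatrix
setMethod("getMatrix", "NoiseCovariance", function(x) x@matrix)
#' @rdname getMatrix
setMethod("getMatrix", "Leadfield", function(x) x@matrix)
#' @rdname getMatrix
setMethod("getMatrix", "InverseOperator", function(x) x@matrix)
#' @rdname getMatrix
setMethod("getMatrix", "ResolutionMatrix", function(x) x@matrix)
#' @rdname InverseOperator-class
setMethod("methodTag", "InverseOperator", function(x) x@method)
#' @rdname InverseOperator-class
setMethod("normWeights", "InverseOperator", function(x) x@weights)
#' @rdname metricValues
setMethod("metricValues", "MetricMaps", function(x, metric) {
  metric <- match.arg(metric, c("dle", "sd", "oa"))
  slot(x, metric)
})

#' Pairwise source distances
#'
#' Euclidean distances between all source pairs.
#' @param x a \code{SourceSpace}.
#' @param units \code{"m"} or \code{"cm"}.
#' @return symmetric [n x n] matrix of distances.
#' @export
sourceDistances <- function(x, units = c("cm", "m")) {
  stopifnot(is(x, "SourceSpace"))
  units <- match.arg(units)
  d <- as.matrix(dist(x@positions))
  dimnames(d) <- NULL
  if (units == "cm") d * 100 else d
}

setMethod("show", "SensorArray", function(object) {
  cat(sprintf("SensorArray '%s': %d channels (%d mag, %d grad), baseline %.1f mm\n",
              object@id, nChannels(object), sum(object@types == "mag"),
              sum(object@types == "grad"), 1000 * object@gradBaseline))
})

setMethod("show", "SourceSpace", function(object) {
  cat(sprintf("SourceSpace '%s': %d sources, depth %.1f-%.1f mm below scalp (conductor R = %.0f mm)\n",
              object@templateId, nSources(object), 1000 * min(object@depth),
              1000 * max(object@depth), 1000 * object@conductorRadius))
})

setMethod("show", "NoiseCovariance", function(object) {
  cat(sprintf("NoiseCovariance '%s': %d channels, %d samples, nAverages = %d\n",
              object@id, nrow(object@matrix), object@nSamples, object@nAverages))
})

setMethod("show", "Leadfield", function(object) {
  cat(sprintf("Leadfield: %d channels x %d sources (sensors '%s', sources '%s')\n",
              nrow(object@matrix), ncol(object@matrix), object@sensorRef,
              object@sourceRef))
})

setMethod("show", "InverseOperator", function(object) {
  cat(sprintf("InverseOperator (%s): %d sources x %d channels, lambda = %.4g, snr = %.3g\n",
              object@method, nrow(object@matrix), ncol(object@matrix),
              object@lambda, object@snr))
})

setMethod("show", "ResolutionMatrix", function(object) {
  cat(sprintf("ResolutionMatrix (%s): %d x %d\n", object@method,
              nrow(object@matrix), ncol(object@matrix)))
})

setMethod("show", "MetricMaps", function(object) {
  cat(sprintf("MetricMaps (%s, %s, subject '%s'): %d sources; DLE mean %.3g cm, SD mean %.3g sqrt-cm\n",
              object@method, object@mode, object@subjectId, length(object@dle),
              mean(object@dle), mean(object@sd)))
})

setMethod("show", "GroupResult", function(object) {
  cat(sprintf("GroupResult %s - %s on %s (%s), n = %d: %d/%d vertices p < 0.05\n",
              object@contrast[1], object@contrast[2], object@contrast[3],
              object@contrast[4], object@nSubjects,
              sum(object@pMap < 0.05), length(object@pMap)))
})
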