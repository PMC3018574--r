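# Group-level aggregation: grand averages, difference maps, across-subject
# SDs and paired two-tailed t-test maps on the shared template.

# stack one metric from a list of MetricMaps into a subjects x vertices matrix
.stackMetric <- function(maps, metric) {
  lens <- vapply(maps, function(m) length(metricValues(m, metric)), integer(1))
  if (length(unique(lens)) != 1L) stop("mismatched vertex counts across subjects")
  do.call(rbind, lapply(maps, metricValues, metric = metric))
}

#' Grand average of per-subject metric maps
#'
#' Vertex-wise arithmetic mean across subjects; all subjects must share the
#' template vertex correspondence.
#'
#' @param maps list of \code{MetricMaps}, one per subject.
#' @param metric \code{"dle"}, \code{"sd"} or \code{"oa"}.
#' @return numeric vector, one value per template vertex.
#' @export
grandAverage <- function(maps, metric = c("dle", "sd", "oa")) {
  metric <- match.arg(metric)
  colMeans(.stackMetric(maps, metric))
}

#' Between-method difference maps
#'
#' Vertex-wise per-subject difference A - B for one metric, plus its grand
#' average. Subjects must be paired (same order, same template).
#'
#' @param mapsA,mapsB lists of \code{MetricMaps} for methods A and B, one
#'   per subject, in the same subject order.
#' @param metric \code{"dle"}, \code{"sd"} or \code{"oa"}.
#' @return list with \code{perSubject} (subjects x vertices matrix) and
#'   \code{mean} (vertex-wise grand-averaged difference).
#' @export
differenceMap <- function(mapsA, mapsB, metric = c("dle", "sd", "oa")) {
  metric <- match.arg(metric)
  if (length(mapsA) != length(mapsB)) stop("subject lists differ in length")
  dd <- .stackMetric(mapsA, metric) - .stackMetric(mapsB, metric)
  list(perSubject = dd, mean = colMeans(dd))
}

#' Across-subject standard deviation
#'
#' Vertex-wise sample standard deviation (n - 1 denominator) of per-subject
#' difference maps.
#'
#' @param differences subjects x vertices numeric matrix (e.g.
#'   \code{differenceMap(...)$perSubject}).
#' @return numeric vector of SDs per vertex.
#' @export
acrossSubjectSD <- function(differences) {
  if (!is.matrix(differences) || nrow(differences) < 2L)
    stop("need a matrix with at least 2 subjects")
  apply(differences, 2, sd)
}

#' Paired two-tailed t-test map
#'
#' Vertex-wise paired t statistic \eqn{t = \bar{d} / (s_d / \sqrt{n})} and
#' two-tailed p value under Student's t with n - 1 degrees of freedom, for
#' the contrast A - B. Vertices where the difference has zero variance
#' across subjects are flagged degenerate and get p = 1 when the mean
#' difference is 0 (identical maps, e.g. CTF-mode contrasts) and p = 0
#' otherwise; this convention keeps theoretically-identical contrasts from
#' producing NaNs.
#'
#' @inheritParams differenceMap
#' @param mode label stored in the contrast (PSF or CTF).
#' @return a \code{\linkS4class{GroupResult}}.
#' @export
pairedTTestMap <- function(mapsA, mapsB, metric = c("dle", "sd", "oa"),
                           mode = "PSF") {
  metric <- match.arg(metric)
  n <- length(mapsA)
  if (n < 2L) stop("paired t-test needs at least 2 subjects")
  d <- differenceMap(mapsA, mapsB, metric)$perSubject
  m <- colMeans(d)
  s <- apply(d, 2, sd)
  degen <- s == 0
  tval <- ifelse(degen, ifelse(m == 0, 0, sign(m) * Inf),
                 m / (s / sqrt(n)))
  pval <- ifelse(degen, ifelse(m == 0, 1, 0),
                 2 * pt(abs(tval), df = n - 1, lower.tail = FALSE))
  if (any(degen))
    message(sum(degen), " vertex/vertices with zero-variance differences (degenerate p convention applied)")
  new("GroupResult", meanMap = m, sdMap = s, tMap = as.numeric(tval),
      pMap = as.numeric(pval), degenerate = degen,
      contrast = c(mapsA[[1]]@method, mapsB[[1]]@method, metric, mode),
      nSubjects = as.integer(n))
}
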