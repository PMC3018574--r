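# Analytic spherical-conductor MEG forward model (Sarvas solution) and
# sensitivity maps.

# Vectorized Sarvas evaluation: magnetic field at one external point `rv`
# (3-vector, relative to the sphere center) from n dipoles with positions
# `R0` (n x 3, relative to center) and moments `Q` (n x 3, A*m).
# Returns n x 3 fields in tesla. The analytic solution is independent of
# the sphere radius and conductivity.
.sarvasMany <- function(rv, R0, Q) {
  rn <- sqrt(sum(rv^2))
  A <- matrix(rv, nrow(R0), 3, byrow = TRUE) - R0        # a = r - r0
  a <- .rowNorms(A)
  if (any(a == 0)) stop("field point coincides with a dipole position")
  r0dotr <- as.numeric(R0 %*% rv)
  adotr <- as.numeric(A %*% rv)
  FF <- a * (rn * a + rn^2 - r0dotr)
  c1 <- a^2 / rn + adotr / a + 2 * a + 2 * rn
  c2 <- a + 2 * rn + adotr / a
  gradF <- outer(c1, rv) - c2 * R0
  QxR0 <- .rowCross(Q, R0)
  qr <- as.numeric(QxR0 %*% rv)
  1e-7 * (FF * QxR0 - qr * gradF) / FF^2
}

#' Magnetic field of a current dipole in a spherical conductor
#'
#' Analytic (Sarvas) solution for the magnetic field outside a homogeneous
#' spherical conductor, which depends only on the dipole, the field point
#' and the sphere center, not on the sphere radius or conductivity.
#' Radially oriented dipoles and dipoles at the center are magnetically
#' silent (zero field everywhere outside).
#'
#' @param dipolePosition 3-vector, dipole location (m).
#' @param dipoleMoment 3-vector, dipole moment (A*m).
#' @param fieldPoint 3-vector, measurement point (m); must be farther from
#'   the center than the dipole.
#' @param sphereCenter 3-vector, conductor center (default origin).
#' @return 3-vector magnetic field in tesla.
#' @examples
#' # a radial dipole is silent:
#' sarvasField(c(0, 0, 0.07), c(0, 0, 1e-9), c(0.1, 0, 0.1))
#' @export
sarvasField <- function(dipolePosition, dipoleMoment, fieldPoint,
                        sphereCenter = c(0, 0, 0)) {
  stopifnot(length(dipolePosition) == 3, length(dipoleMoment) == 3,
            length(fieldPoint) == 3, length(sphereCenter) == 3)
  r0 <- dipolePosition - sphereCenter
  rv <- fieldPoint - sphereCenter
  if (sum(rv^2) <= sum(r0^2))
    stop("field point must lie outside the sphere containing the dipole")
  if (all(fieldPoint == dipolePosition))
    stop("field point coincides with the dipole")
  as.numeric(.sarvasMany(rv, matrix(r0, 1), matrix(dipoleMoment, 1)))
}

#' Response of a single channel to a dipole
#'
#' Magnetometers project the field onto the channel orientation; planar
#' gradiometers take the difference of that projection at the two
#' integration points (\code{+/- baseline/2} along the gradiometer axis)
#' divided by the baseline.
#'
#' @param sensorArray a \code{SensorArray}.
#' @param channel channel index.
#' @param dipolePosition,dipoleMoment dipole location (m) and moment (A*m).
#' @param sphereCenter conductor center (default origin).
#' @return scalar response (T for magnetometers, T/m for gradiometers).
#' @export
channelResponse <- function(sensorArray, channel, dipolePosition,
                            dipoleMoment, sphereCenter = c(0, 0, 0)) {
  stopifnot(is(sensorArray, "SensorArray"))
  if (channel < 1 || channel > nChannels(sensorArray))
    stop("channel index out of range")
  p <- sensorArray@positions[channel, ]
  o <- sensorArray@orientations[channel, ]
  if (sensorArray@types[channel] == "mag") {
    sum(sarvasField(dipolePosition, dipoleMoment, p, sphereCenter) * o)
  } else {
    b <- sensorArray@gradBaseline
    ax <- sensorArray@axes[channel, ]
    f1 <- sum(sarvasField(dipolePosition, dipoleMoment, p + ax * b / 2,
                          sphereCenter) * o)
    f2 <- sum(sarvasField(dipolePosition, dipoleMoment, p - ax * b / 2,
                          sphereCenter) * o)
    (f1 - f2) / b
  }
}

#' Build the leadfield matrix
#'
#' Entry (c, j) is the response of channel c to a unit dipole at source j
#' oriented along its surface normal (fixed-orientation model, no depth
#' weighting). Orientations are re-normalized to unit length so amplitude
#' is never encoded in the orientation vectors.
#'
#' @param sensorArray a \code{SensorArray}; every integration point must
#'   lie strictly outside the conductor sphere.
#' @param sourceSpace a \code{SourceSpace}.
#' @param sphereCenter conductor center (default origin).
#' @return a \code{\linkS4class{Leadfield}} [n_channels x n_sources].
#' @export
buildLeadfield <- function(sensorArray, sourceSpace,
                           sphereCenter = c(0, 0, 0)) {
  stopifnot(is(sensorArray, "SensorArray"), is(sourceSpace, "SourceSpace"))
  R0 <- sweep(sourceSpace@positions, 2, sphereCenter)
  rad <- .rowNorms(R0)
  if (any(rad >= sourceSpace@conductorRadius))
    stop("source(s) outside the conductor sphere")
  Q <- .unitRows(sourceSpace@orientations)
  b <- sensorArray@gradBaseline
  nCh <- nChannels(sensorArray)
  L <- matrix(NA_real_, nCh, nrow(R0))
  for (cix in seq_len(nCh)) {
    p <- sensorArray@positions[cix, ]
    o <- sensorArray@orientations[cix, ]
    if (sensorArray@types[cix] == "mag") {
      pts <- list(p)
    } else {
      ax <- sensorArray@axes[cix, ]
      pts <- list(p + ax * b / 2, p - ax * b / 2)
    }
    proj <- lapply(pts, function(pt) {
      pc <- pt - sphereCenter
      if (sqrt(sum(pc^2)) <= sourceSpace@conductorRadius)
        stop("sensor integration point not strictly outside the conductor sphere")
      as.numeric(.sarvasMany(pc, R0, Q) %*% o)
    })
    L[cix, ] <- if (length(proj) == 1L) proj[[1]] else (proj[[1]] - proj[[2]]) / b
  }
  new("Leadfield", matrix = L, sensorRef = sensorArray@id,
      sourceRef = sourceSpace@templateId)
}

#' Leadfield sensitivity map
#'
#' Per-source sum of squares of the corresponding leadfield column,
#' optionally normalized to its maximum over sources. Sensitivity drops
#' with source depth, mirroring the superficial bias of MEG.
#'
#' @param leadfield a \code{Leadfield}.
#' @param normalize divide by the maximum over sources (default TRUE).
#' @return numeric vector, one value per source.
#' @export
sensitivityMap <- function(leadfield, normalize = TRUE) {
  stopifnot(is(leadfield, "Leadfield"))
  L <- getMatrix(leadfield)
  if (length(L) == 0) stop("empty leadfield")
  s <- colSums(L^2)
  if (normalize) {
    m <- max(s)
    if (m == 0) stop("all-zero leadfield cannot be normalized")
    s <- s / m
  }
  s
}
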