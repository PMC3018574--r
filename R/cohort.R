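# Synthetic cohort generation: sensor arrays, folded source spaces,
# per-subject geometric jitter and simulated baseline noise covariances.

#' Generate a synthetic MEG sensor array
#'
#' Places sensor sites quasi-uniformly (Fibonacci lattice) over the upper
#' hemisphere of a helmet of radius \code{helmetRadius}, with a seeded
#' azimuthal rotation. Each site can carry one magnetometer and/or a pair of
#' co-located planar gradiometers with orthogonal tangential baselines.
#' All pickup orientations are radial (pointing away from the head center),
#' as for an axial magnetometer / planar gradiometer helmet.
#'
#' @param nMag number of magnetometers (>= 1).
#' @param nGrad number of planar gradiometers (even; placed in pairs).
#' @param helmetRadius helmet radius in meters.
#' @param seed integer seed; the array is a pure function of its arguments.
#' @param gradBaseline planar-gradiometer two-point baseline in meters
#'   (default 16.8 mm).
#' @return a \code{\linkS4class{SensorArray}}.
#' @examples
#' arr <- makeSensorArray(102, 204, 0.12, seed = 1)
#' nChannels(arr)
#' @export
makeSensorArray <- function(nMag, nGrad, helmetRadius, seed,
                            gradBaseline = 0.0168) {
  if (nMag < 1) stop("'nMag' must be >= 1")
  if (nGrad < 0) stop("'nGrad' must be >= 0")
  if (nGrad %% 2 != 0) stop("'nGrad' must be even (planar gradiometer pairs)")
  .assertScalarNum(helmetRadius, "helmetRadius", positive = TRUE)
  .assertScalarNum(gradBaseline, "gradBaseline", positive = TRUE)

  nSites <- max(nMag, nGrad %/% 2)
  az0 <- .withSeed(seed, runif(1, 0, 2 * pi))
  # upper hemisphere, z in (0.05, 1): avoid the helmet rim itself
  u <- .fibonacciDirections(nSites, zmin = 0.05, zmax = 1, azimuth0 = az0)

  # local tangential frame at each site
  z <- u[, 3]
  s <- sqrt(pmax(1e-300, 1 - z^2))
  phiHat <- cbind(-u[, 2], u[, 1], 0) / s
  thetaHat <- .rowCross(phiHat, u)            # both unit, orthogonal to u

  pos <- ori <- axs <- matrix(0, 0, 3)
  typ <- character()
  nPair <- nGrad %/% 2
  for (i in seq_len(nSites)) {
    p <- helmetRadius * u[i, ]
    if (i <= nPair) {
      pos <- rbind(pos, p, p); ori <- rbind(ori, u[i, ], u[i, ])
      axs <- rbind(axs, thetaHat[i, ], phiHat[i, ])
      typ <- c(typ, "grad", "grad")
    }
    if (i <= nMag) {
      pos <- rbind(pos, p); ori <- rbind(ori, u[i, ]); axs <- rbind(axs, c(0, 0, 0))
      typ <- c(typ, "mag")
    }
  }
  dimnames(pos) <- dimnames(ori) <- dimnames(axs) <- NULL
  new("SensorArray", positions = pos, orientations = .unitRows(ori),
      axes = axs, types = typ, gradBaseline = gradBaseline,
      id = sprintf("helm-%dm%dg-s%d", nMag, nGrad, as.integer(seed)))
}

#' Generate a folded synthetic source space
#'
#' Samples \code{nSources} quasi-uniform directions and places each source
#' on a radially perturbed shell
#' \deqn{r(\theta,\phi) = r_0 - f_d (1 + \sin(k\theta)\sin(k\phi))/2,}
#' where \eqn{r_0 = } \code{conductorRadius - scalpMargin}, \eqn{f_d} is
#' \code{foldDepth} and \eqn{k} is \code{foldFrequency}. The folding mimics
#' gyri and sulci: source depth below the model scalp varies by up to
#' \code{foldDepth}. Orientations are the outward local surface normals of
#' the shell (so dipoles are perpendicular to the synthetic "cortex").
#'
#' @param nSources number of dipoles (>= 2).
#' @param conductorRadius radius of the spherical conductor (m).
#' @param foldDepth fold amplitude in meters (>= 0; 0 gives a sphere).
#' @param foldFrequency angular frequency of the folds.
#' @param seed integer seed (azimuthal lattice rotation).
#' @param scalpMargin distance between the conductor surface and the
#'   shallowest possible source (m); keeps all sources strictly inside the
#'   conductor even after cohort jitter.
#' @return a \code{\linkS4class{SourceSpace}} with the depth field set to
#'   \code{conductorRadius} minus the radial coordinate.
#' @examples
#' src <- makeSourceSpace(500, 0.09, 0.03, 6, seed = 2)
#' range(sourceDepths(src))
#' @export
makeSourceSpace <- function(nSources, conductorRadius, foldDepth,
                            foldFrequency, seed, scalpMargin = 0.01) {
  if (nSources < 2) stop("'nSources' must be >= 2")
  .assertScalarNum(conductorRadius, "conductorRadius", positive = TRUE)
  .assertScalarNum(foldDepth, "foldDepth")
  if (foldDepth < 0 || foldDepth >= conductorRadius)
    stop("'foldDepth' must be in [0, conductorRadius)")
  if (scalpMargin <= 0 || scalpMargin + foldDepth >= conductorRadius)
    stop("sources would fall outside the conductor: reduce foldDepth/scalpMargin")

  az0 <- .withSeed(seed, runif(1, 0, 2 * pi))
  u <- .fibonacciDirections(nSources, zmin = -1, zmax = 1, azimuth0 = az0)
  theta <- acos(pmin(1, pmax(-1, u[, 3])))
  phi <- atan2(u[, 2], u[, 1])
  k <- foldFrequency
  r0 <- conductorRadius - scalpMargin
  rr <- r0 - foldDepth * (1 + sin(k * theta) * sin(k * phi)) / 2
  pos <- rr * u

  # outward normal of the shell r = R(theta, phi):
  # n ~ rhat - (R_theta / R) thetaHat - (R_phi / (R sin theta)) phiHat
  dRdTheta <- -(foldDepth / 2) * k * cos(k * theta) * sin(k * phi)
  dRdPhi <- -(foldDepth / 2) * k * sin(k * theta) * cos(k * phi)
  st <- sin(theta)
  thetaHat <- cbind(cos(theta) * cos(phi), cos(theta) * sin(phi), -st)
  phiHat <- cbind(-sin(phi), cos(phi), 0)
  nrm <- u - (dRdTheta / rr) * thetaHat - (dRdPhi / (rr * pmax(st, 1e-12))) * phiHat
  ori <- .unitRows(nrm)

  new("SourceSpace", positions = pos, orientations = ori,
      depth = conductorRadius - rr, conductorRadius = conductorRadius,
      templateId = sprintf("shell-%d-s%d", nSources, as.integer(seed)))
}

#' Generate a cohort of synthetic subjects
#'
#' Every subject shares the template sensor array and source space defined
#' by \code{baseConfig}; per subject, the sensor array is rotated by a small
#' seeded random rigid rotation (emulating head-position variation in the
#' helmet) and source positions receive i.i.d. Gaussian jitter of standard
#' deviation \code{jitterScale} per coordinate (emulating anatomical
#' variability). Vertex-to-template correspondence is retained, which
#' stands in for surface morphing: group statistics operate vertex-wise on
#' the template index. With \code{jitterScale = 0} all subjects are
#' identical to the template.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param baseConfig list of template parameters; see
#'   \code{\link{defaultStudyConfig}} for keys (n_mag, n_grad, n_sources,
#'   helmet_radius, conductor_radius, scalp_margin, fold_depth,
#'   fold_frequency, gradiometer_baseline).
#' @param jitterScale vertex jitter SD in meters; the rigid-rotation angle
#'   SD is \code{jitterScale / conductor_radius} radians, so zero jitter
#'   means zero perturbation.
#' @param seed integer master seed; subject k draws from a child seed that
#'   does not depend on nSubjects.
#' @return list with elements \code{template} (list: sensors, sources) and
#'   \code{subjects} (list of per-subject lists: sensors, sources, id).
#' @export
makeCohort <- function(nSubjects, baseConfig = defaultStudyConfig(),
                       jitterScale = 0.002, seed = 1) {
  if (nSubjects < 2) stop("'nSubjects' must be >= 2 (group statistics need df >= 1)")
  if (jitterScale < 0) stop("'jitterScale' must be >= 0")
  cfg <- baseConfig
  sens <- makeSensorArray(cfg$n_mag, cfg$n_grad, cfg$helmet_radius,
                          seed = .childSeed(seed, 0L, 1L),
                          gradBaseline = cfg$gradiometer_baseline)
  srcs <- makeSourceSpace(cfg$n_sources, cfg$conductor_radius, cfg$fold_depth,
                          cfg$fold_frequency, seed = .childSeed(seed, 0L, 2L),
                          scalpMargin = cfg$scalp_margin)
  subjects <- lapply(seq_len(nSubjects), function(k) {
    .withSeed(.childSeed(seed, k, 3L), {
      if (jitterScale > 0) {
        ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
        ang <- rnorm(1, 0, jitterScale / cfg$conductor_radius)
        Rm <- .rotationMatrix(ax, ang)
        sensK <- new("SensorArray",
                     positions = sens@positions %*% t(Rm),
                     orientations = sens@orientations %*% t(Rm),
                     axes = sens@axes %*% t(Rm), types = sens@types,
                     gradBaseline = sens@gradBaseline,
                     id = sprintf("%s-sub%02d", sens@id, k))
        jit <- matrix(rnorm(3 * nSources(srcs), 0, jitterScale),
                      nSources(srcs), 3)
        pos <- srcs@positions + jit
        r <- .rowNorms(pos)
        if (any(r >= cfg$conductor_radius))
          stop("jitter pushed ", sum(r >= cfg$conductor_radius),
               " source(s) outside the conductor; reduce jitterScale")
        srcK <- new("SourceSpace", positions = pos,
                    orientations = srcs@orientations,
                    depth = cfg$conductor_radius - r,
                    conductorRadius = srcs@conductorRadius,
                    templateId = srcs@templateId)
      } else {
        sensK <- sens; srcK <- srcs
      }
      list(sensors = sensK, sources = srcK, id = sprintf("sub%02d", k))
    })
  })
  list(template = list(sensors = sens, sources = srcs), subjects = subjects)
}

#' Simulate a baseline noise covariance
#'
#' Draws \code{nTrials * round(samplingRate * baselineDuration)} samples of
#' sensor noise as a mixture of i.i.d. white sensor noise and "brain noise"
#' (random source activity projected through the leadfield), concatenates
#' them as in trial-wise baseline estimation, and returns their sample
#' covariance (mean-subtracted, n-1 denominator). The brain component is
#' rescaled so the average per-channel variance equals
#' \code{sensorNoiseSD^2} regardless of \code{brainNoiseFraction}; with
#' \code{brainNoiseFraction = 0} the covariance converges to
#' \code{sensorNoiseSD^2} times the identity.
#'
#' @param sensorArray the \code{SensorArray} (defines channel count).
#' @param leadfield a \code{Leadfield} for the brain-noise projection.
#' @param nTrials number of trials (>= 1).
#' @param baselineDuration baseline length per trial in seconds.
#' @param samplingRate sampling rate in Hz.
#' @param brainNoiseFraction fraction in [0, 1] of noise variance routed
#'   through the leadfield.
#' @param seed integer seed.
#' @param sensorNoiseSD white sensor-noise standard deviation (default 1).
#' @param nAverages trial-averaging divisor stored for dSPM weighting
#'   (default 100).
#' @return a \code{\linkS4class{NoiseCovariance}}.
#' @export
simulateNoiseCovariance <- function(sensorArray, leadfield, nTrials,
                                    baselineDuration, samplingRate,
                                    brainNoiseFraction, seed,
                                    sensorNoiseSD = 1, nAverages = 100L) {
  stopifnot(is(sensorArray, "SensorArray"), is(leadfield, "Leadfield"))
  if (nTrials < 1) stop("'nTrials' must be >= 1")
  perTrial <- round(samplingRate * baselineDuration)
  if (perTrial < 1) stop("samplingRate * baselineDuration must be >= 1 sample")
  if (brainNoiseFraction < 0 || brainNoiseFraction > 1)
    stop("'brainNoiseFraction' must be in [0, 1]")
  nCh <- nChannels(sensorArray)
  L <- getMatrix(leadfield)
  if (nrow(L) != nCh) stop("leadfield channel count does not match sensor array")
  nSamp <- as.integer(nTrials * perTrial)
  if (nSamp <= 1) stop("need at least 2 samples for a covariance estimate")

  X <- .withSeed(seed, {
    E <- matrix(rnorm(nSamp * nCh, 0, sensorNoiseSD), nSamp, nCh)
    if (brainNoiseFraction > 0) {
      Q <- matrix(rnorm(nSamp * ncol(L)), nSamp, ncol(L))
      B <- Q %*% t(L)
      B <- B * (sensorNoiseSD / sqrt(mean(rowSums(L^2))))
      sqrt(1 - brainNoiseFraction) * E + sqrt(brainNoiseFraction) * B
    } else E
  })
  C <- cov(X)
  C <- (C + t(C)) / 2
  dimnames(C) <- NULL
  kap <- kappa(C, exact = FALSE)
  if (kap > 1e12)
    warning(sprintf("noise covariance is ill-conditioned (kappa ~ %.3g)", kap))
  new("NoiseCovariance", matrix = C, nSamples = nSamp,
      nAverages = as.integer(nAverages),
      id = sprintf("cov-%dx%d-s%d", nCh, nSamp, as.integer(seed)))
}
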