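# Shared fixtures: small random linear systems and small synthetic
# geometries, built in code at test time.

# random leadfield + SPD covariance + MNE/dSPM/sLORETA operators
randomSystem <- function(seed, nch = 8, nsrc = 20, lambda = NULL) {
  set.seed(seed)
  L <- matrix(rnorm(nch * nsrc), nch, nsrc)
  X <- matrix(rnorm(5 * nch * nch), 5 * nch, nch)
  C <- cov(X); C <- (C + t(C)) / 2; dimnames(C) <- NULL
  lf <- new("Leadfield", matrix = L, sensorRef = "test", sourceRef = "test")
  nc <- new("NoiseCovariance", matrix = C, nSamples = nrow(X),
            nAverages = 100L, id = "test")
  if (is.null(lambda)) lambda <- regularizationLambda(lf, nc, 3)
  mne <- suppressMessages(mneOperator(lf, nc, lambda = lambda))
  list(L = L, C = C, lf = lf, nc = nc, lambda = lambda, mne = mne)
}

# wrap a plain matrix as a Leadfield / NoiseCovariance / ResolutionMatrix
asLeadfield <- function(L) new("Leadfield", matrix = L, sensorRef = "t",
                               sourceRef = "t")
asNoiseCov <- function(C, nAverages = 1L)
  new("NoiseCovariance", matrix = (C + t(C)) / 2, nSamples = 10L,
      nAverages = as.integer(nAverages), id = "t")
asResMat <- function(R, method = "MNE")
  new("ResolutionMatrix", matrix = R, method = method, sourceRef = "t")

# a SourceSpace with given positions (orientations irrelevant for metrics)
posSpace <- function(positions, conductorRadius = 1) {
  n <- nrow(positions)
  o <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  new("SourceSpace", positions = positions, orientations = o,
      depth = conductorRadius - sqrt(rowSums(positions^2)),
      conductorRadius = conductorRadius, templateId = "t")
}

# small but physically sensible geometry + full operator set
smallStudySystem <- function(seed = 11, nMag = 30, nGrad = 0, nsrc = 80) {
  arr <- makeSensorArray(nMag, nGrad, 0.12, seed = seed)
  src <- makeSourceSpace(nsrc, 0.09, 0.03, 6, seed = seed + 1)
  lf <- buildLeadfield(arr, src)
  nc <- simulateNoiseCovariance(arr, lf, 20, 0.2, 100, 0.3, seed = seed + 2)
  mne <- suppressMessages(mneOperator(lf, nc))
  dspm <- applyNormalization(mne, dspmWeights(mne, nc), "dSPM")
  slor <- applyNormalization(mne, sloretaWeights(mne, lf), "sLORETA")
  list(arr = arr, src = src, lf = lf, nc = nc, mne = mne, dspm = dspm,
       slor = slor)
}

# MetricMaps with prescribed values (for group-level tests)
mapsFromValues <- function(values, method = "MNE", mode = "PSF",
                           subject = "s") {
  n <- length(values)
  new("MetricMaps", mode = mode, method = method, subjectId = subject,
      dle = values, sd = values, oa = values / max(values))
}
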