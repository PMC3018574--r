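# Resolution matrix, PSF/CTF extraction and the DLE/SD/OA metrics.

test_that("resolution matrix columns are operator applications, exactly", {
  sys <- randomSystem(5)
  R <- resolutionMatrix(sys$mne, sys$lf)
  for (j in seq_len(ncol(sys$L)))
    expect_identical(getMatrix(R)[, j], applyInverse(sys$mne, sys$L[, j]))
  # square invertible L with G = L^-1 gives R = I
  set.seed(6)
  L <- matrix(rnorm(25), 5, 5) + 5 * diag(5)
  op <- new("InverseOperator", matrix = solve(L), method = "MNE", lambda = 0,
            snr = 3, weights = rep(1, 5), noiseRef = "t")
  expect_equal(getMatrix(resolutionMatrix(op, asLeadfield(L))), diag(5),
               tolerance = 1e-12)
})

test_that("the MNE resolution matrix is symmetric; PSFs equal CTFs", {
  sys <- randomSystem(7, nch = 12, nsrc = 30)
  R <- getMatrix(resolutionMatrix(sys$mne, sys$lf))
  expect_lt(max(abs(R - t(R))) / max(abs(R)), 1e-10)
  Robj <- resolutionMatrix(sys$mne, sys$lf)
  for (i in c(1, 10, 30))
    expect_equal(psf(Robj, i), ctf(Robj, i), tolerance = 1e-10)
})

test_that("row normalization rescales CTFs but reshapes only PSFs", {
  sys <- randomSystem(8, nch = 10, nsrc = 25)
  w <- dspmWeights(sys$mne, sys$nc)
  dspm <- applyNormalization(sys$mne, w, "dSPM")
  Rm <- resolutionMatrix(sys$mne, sys$lf)
  Rd <- resolutionMatrix(dspm, sys$lf)
  for (i in seq_len(25)) {
    # CTF_i is w_i times the MNE CTF_i: cosine similarity 1
    a <- ctf(Rd, i); b <- ctf(Rm, i)
    expect_equal(sum(a * b) / sqrt(sum(a^2) * sum(b^2)), 1, tolerance = 1e-12)
    expect_equal(a, w[i] * b, tolerance = 1e-12)
  }
  # PSF_i is the elementwise product of the weight vector with the MNE PSF
  expect_equal(psf(Rd, 3), w * psf(Rm, 3), tolerance = 1e-12)
  expect_error(psf(Rm, 26), "range")
  expect_error(ctf(Rm, 0), "range")
})

test_that("localization error measures peak displacement in centimeters", {
  pos <- cbind(c(0, 0.01, 0.02), 0, 0)   # collinear at 0, 1, 2 cm
  spc <- posSpace(pos)
  expect_equal(localizationError(c(0.1, 0.2, 1.0), 1, spc), 2.0)
  expect_equal(localizationError(c(1, 0, 0), 1, spc), 0)
  # sign is irrelevant: peak of |F|
  expect_equal(localizationError(c(0.1, -5, 0.2), 3, spc), 1.0)
  expect_error(localizationError(c(0, 0, 0), 1, spc), "zero")
  expect_message(localizationError(c(1, 1, 0), 1, spc), "tied")

  # brute-force argmax-and-distance oracle on random vectors
  set.seed(9)
  rpos <- matrix(runif(30 * 3, -0.05, 0.05), 30, 3)
  rspc <- posSpace(rpos)
  for (k in 1:10) {
    f <- rnorm(30); ti <- sample(30, 1)
    best <- 1
    for (j in 2:30) if (abs(f[j]) > abs(f[best])) best <- j
    ref <- 100 * sqrt(sum((rpos[best, ] - rpos[ti, ])^2))
    expect_identical(localizationError(f, ti, rspc), ref)
  }
})

test_that("spatial dispersion is the amplitude-weighted RMS-distance root", {
  pos <- cbind(c(0, 0.01), 0, 0)     # two sources 1 cm apart
  spc <- posSpace(pos)
  expect_equal(spatialDispersion(c(1, 1), 1, spc), sqrt(0.5))
  expect_equal(spatialDispersion(c(1, 0), 1, spc), 0)
  expect_error(spatialDispersion(c(0, 0), 1, spc), "zero")

  # independent summation-loop oracle
  set.seed(10)
  rpos <- matrix(runif(25 * 3, -0.05, 0.05), 25, 3)
  rspc <- posSpace(rpos)
  for (k in 1:10) {
    f <- rnorm(25); ti <- sample(25, 1)
    num <- 0; den <- 0
    for (j in 1:25) {
      dij <- 100 * sqrt(sum((rpos[j, ] - rpos[ti, ])^2))
      num <- num + dij * f[j]^2
      den <- den + f[j]^2
    }
    expect_equal(spatialDispersion(f, ti, rspc), sqrt(num / den),
                 tolerance = 1e-12)
  }
  # exponent 1 variant weights by |F|
  f <- c(1, 3)
  expect_equal(spatialDispersion(f, 1, spc, exponent = 1), sqrt(1 * 3 / 4))
})

test_that("overall amplitude sums absolute values", {
  expect_equal(overallAmplitude(c(1, -2, 3)), 6)
  expect_equal(overallAmplitude(rep(0, 5)), 0)
  set.seed(11)
  f <- rnorm(40)
  ref <- 0; for (v in f) ref <- ref + abs(v)
  expect_equal(overallAmplitude(f), ref, tolerance = 1e-14)
})

test_that("metric maps aggregate per-source metrics and normalize OA", {
  set.seed(12)
  pos <- matrix(runif(15 * 3, -0.05, 0.05), 15, 3)
  spc <- posSpace(pos)
  # identity resolution: perfect localization, zero spread, flat amplitude
  mm <- metricMaps(asResMat(diag(15)), "PSF", spc)
  expect_equal(metricValues(mm, "dle"), rep(0, 15))
  expect_equal(metricValues(mm, "sd"), rep(0, 15))
  expect_equal(metricValues(mm, "oa"), rep(1, 15))

  # maps agree with per-source scalar-metric loops
  R <- matrix(rnorm(15 * 15), 15, 15)
  for (mode in c("PSF", "CTF")) {
    mm2 <- metricMaps(asResMat(R), mode, spc)
    expect_identical(max(metricValues(mm2, "oa")), 1)
    for (i in c(2, 9, 15)) {
      f <- if (mode == "PSF") R[, i] else R[i, ]
      expect_equal(metricValues(mm2, "dle")[i], localizationError(f, i, spc),
                   tolerance = 1e-12)
      expect_equal(metricValues(mm2, "sd")[i], spatialDispersion(f, i, spc),
                   tolerance = 1e-12)
    }
    oaRaw <- vapply(seq_len(15), function(i)
      overallAmplitude(if (mode == "PSF") R[, i] else R[i, ]), numeric(1))
    expect_equal(metricValues(mm2, "oa"), oaRaw / max(oaRaw),
                 tolerance = 1e-12)
  }
})

test_that("MNE metric maps coincide between PSF and CTF modes", {
  sys <- smallStudySystem(seed = 51, nMag = 25, nsrc = 60)
  Rm <- resolutionMatrix(sys$mne, sys$lf)
  mP <- metricMaps(Rm, "PSF", sys$src)
  mC <- metricMaps(Rm, "CTF", sys$src)
  expect_equal(metricValues(mP, "dle"), metricValues(mC, "dle"),
               tolerance = 1e-10)
  expect_equal(metricValues(mP, "sd"), metricValues(mC, "sd"),
               tolerance = 1e-10)
  expect_equal(metricValues(mP, "oa"), metricValues(mC, "oa"),
               tolerance = 1e-10)
})

test_that("CTF-mode DLE and SD are identical across methods", {
  sys <- smallStudySystem(seed = 52, nMag = 25, nsrc = 60)
  maps <- lapply(list(sys$mne, sys$dspm, sys$slor), function(op)
    metricMaps(resolutionMatrix(op, sys$lf), "CTF", sys$src))
  for (m in c("dle", "sd")) {
    v <- lapply(maps, metricValues, metric = m)
    expect_equal(v[[2]], v[[1]], tolerance = 1e-10)
    expect_equal(v[[3]], v[[1]], tolerance = 1e-10)
  }
  # CTFs of any two methods are positively proportional
  Rs <- lapply(list(sys$mne, sys$dspm, sys$slor), function(op)
    resolutionMatrix(op, sys$lf))
  for (i in c(1, 30, 60)) {
    a <- ctf(Rs[[2]], i); b <- ctf(Rs[[3]], i)
    expect_equal(sum(a * b) / sqrt(sum(a^2) * sum(b^2)), 1, tolerance = 1e-12)
  }
})

test_that("sLORETA PSFs peak at the true source (zero DLE) on generated systems", {
  for (seed in c(61, 62, 63)) {
    sys <- smallStudySystem(seed = seed, nMag = 20, nsrc = 50)
    mm <- metricMaps(resolutionMatrix(sys$slor, sys$lf), "PSF", sys$src)
    expect_identical(max(metricValues(mm, "dle")), 0)
  }
})

test_that("a near-unregularized square system recovers the identity limit", {
  set.seed(13)
  n <- 12
  L <- matrix(rnorm(n * n), n, n) + 4 * diag(n)
  lf <- asLeadfield(L)
  nc <- asNoiseCov(diag(n))
  lam <- 1e-14 * sum(L^2)
  mne <- suppressMessages(mneOperator(lf, nc, lambda = lam))
  pos <- matrix(runif(n * 3, -0.04, 0.04), n, 3)
  spc <- posSpace(pos)
  ops <- list(mne,
              applyNormalization(mne, dspmWeights(mne, nc), "dSPM"),
              applyNormalization(mne, sloretaWeights(mne, lf), "sLORETA"))
  R <- getMatrix(resolutionMatrix(mne, lf))
  expect_lt(max(abs(R - diag(n))), 1e-6)
  for (op in ops) {
    mm <- metricMaps(resolutionMatrix(op, lf), "PSF", spc)
    expect_identical(max(metricValues(mm, "dle")), 0)
    expect_lt(max(metricValues(mm, "sd")), 1e-3)
  }
})
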