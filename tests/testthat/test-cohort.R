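# Synthetic cohort generators: sensor arrays, folded source spaces,
# subject jitter, simulated noise covariances.

test_that("sensor arrays have the requested composition and geometry", {
  arr <- makeSensorArray(102, 204, 0.12, seed = 1)
  expect_equal(nChannels(arr), 306)
  expect_equal(sum(channelTypes(arr) == "mag"), 102)
  expect_equal(sum(channelTypes(arr) == "grad"), 204)
  expect_true(all(abs(sqrt(rowSums(channelOrientations(arr)^2)) - 1) < 1e-12))

  # all sites on the helmet, distinct: brute-force pairwise check
  arr10 <- makeSensorArray(10, 0, 0.12, seed = 7)
  p <- channelPositions(arr10)
  expect_equal(sqrt(rowSums(p^2)), rep(0.12, 10), tolerance = 1e-12)
  dmin <- Inf
  for (i in 1:9) for (j in (i + 1):10)
    dmin <- min(dmin, sqrt(sum((p[i, ] - p[j, ])^2)))
  expect_gt(dmin, 0)

  # gradiometer pairs are co-located with orthogonal tangential axes
  g <- which(channelTypes(arr) == "grad")
  g1 <- g[1]; g2 <- g[2]
  expect_equal(channelPositions(arr)[g1, ], channelPositions(arr)[g2, ])
  expect_lt(abs(sum(arr@axes[g1, ] * arr@axes[g2, ])), 1e-12)
  expect_lt(abs(sum(arr@axes[g1, ] * channelOrientations(arr)[g1, ])), 1e-12)
})

test_that("sensor array generation is deterministic and validates input", {
  a1 <- makeSensorArray(1, 0, 0.12, seed = 0)
  a2 <- makeSensorArray(1, 0, 0.12, seed = 0)
  expect_identical(channelPositions(a1), channelPositions(a2))
  expect_error(makeSensorArray(0, 0, 0.12, seed = 1), "nMag")
  expect_error(makeSensorArray(2, 0, -1, seed = 1), "helmetRadius")
  expect_error(makeSensorArray(2, 3, 0.12, seed = 1), "even")
})

test_that("source spaces are folded shells with surface-normal orientations", {
  src <- makeSourceSpace(1000, 0.09, 0.03, 6, seed = 2)
  expect_equal(nSources(src), 1000)
  expect_gte(diff(range(sourceDepths(src))), 0.02)
  expect_true(all(sqrt(rowSums(sourcePositions(src)^2)) < 0.09))
  expect_true(all(abs(sqrt(rowSums(sourceOrientations(src)^2)) - 1) < 1e-12))

  # zero fold amplitude: a sphere, depth identical everywhere, radial normals
  sph <- makeSourceSpace(2, 0.09, 0.0, 0, seed = 0)
  r <- sqrt(rowSums(sourcePositions(sph)^2))
  expect_equal(r, rep(r[1], 2), tolerance = 1e-15)
  expect_equal(sourceDepths(sph), rep(sourceDepths(sph)[1], 2))
  u <- sourcePositions(sph) / r
  expect_equal(u, sourceOrientations(sph), tolerance = 1e-12)

  # determinism
  s1 <- makeSourceSpace(50, 0.09, 0.03, 6, seed = 4)
  s2 <- makeSourceSpace(50, 0.09, 0.03, 6, seed = 4)
  expect_identical(sourcePositions(s1), sourcePositions(s2))
  expect_error(makeSourceSpace(1, 0.09, 0.03, 6, seed = 1), "nSources")
  expect_error(makeSourceSpace(10, 0.09, 0.09, 6, seed = 1), "foldDepth")
})

test_that("cohorts share the template and respect the jitter contract", {
  cfg <- defaultStudyConfig()
  cfg$n_mag <- 10L; cfg$n_grad <- 0L; cfg$n_sources <- 60L
  coh <- makeCohort(5, cfg, jitterScale = 0.002, seed = 3)
  expect_length(coh$subjects, 5)
  counts <- vapply(coh$subjects, function(s) nSources(s$sources), integer(1))
  expect_true(all(counts == 60L))
  tids <- vapply(coh$subjects, function(s) templateId(s$sources), character(1))
  expect_true(all(tids == templateId(coh$template$sources)))

  # zero jitter: all subjects identical to the template
  coh0 <- makeCohort(2, cfg, jitterScale = 0, seed = 0)
  expect_identical(sourcePositions(coh0$subjects[[1]]$sources),
                   sourcePositions(coh0$subjects[[2]]$sources))
  expect_identical(channelPositions(coh0$subjects[[1]]$sensors),
                   channelPositions(coh0$template$sensors))

  # adding subjects does not perturb earlier subjects' draws
  coh6 <- makeCohort(6, cfg, jitterScale = 0.002, seed = 3)
  expect_identical(sourcePositions(coh$subjects[[2]]$sources),
                   sourcePositions(coh6$subjects[[2]]$sources))

  expect_error(makeCohort(1, cfg, 0.002, 1), "nSubjects")
  expect_error(makeCohort(3, cfg, jitterScale = 0.2, seed = 1), "outside")
})

test_that("simulated noise covariances are symmetric PSD sample covariances", {
  sys <- smallStudySystem(seed = 21, nMag = 12, nsrc = 30)
  nc <- simulateNoiseCovariance(sys$arr, sys$lf, 146, 0.2, 250, 0.5, seed = 5)
  expect_equal(nc@nSamples, 146L * 50L)
  C <- getMatrix(nc)
  expect_identical(max(abs(C - t(C))), 0)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) >= -1e-10 * sum(diag(C)))

  # two-pass sample-covariance oracle on a tiny draw: recompute the exact
  # sample stream and its covariance by explicit loops
  # 6 samples for 12 channels: rank deficient, must warn about conditioning
  expect_warning(
    ncSmall <- simulateNoiseCovariance(sys$arr, sys$lf, 3, 0.2, 10, 0, seed = 9),
    "ill-conditioned")
  nch <- nChannels(sys$arr)
  set.seed(9)
  X <- matrix(rnorm(6 * nch), 6, nch)
  Cref <- matrix(0, nch, nch)
  mu <- colSums(X) / 6
  for (a in seq_len(nch)) for (b in seq_len(nch))
    Cref[a, b] <- sum((X[, a] - mu[a]) * (X[, b] - mu[b])) / 5
  expect_equal(getMatrix(ncSmall), (Cref + t(Cref)) / 2, tolerance = 1e-12)

  # white-noise limit: off-diagonals within 5 standard errors of zero
  ncW <- simulateNoiseCovariance(sys$arr, sys$lf, 2000, 0.2, 50, 0, seed = 6)
  CW <- getMatrix(ncW)
  se <- 1 / sqrt(ncW@nSamples)
  off <- CW[upper.tri(CW)]
  expect_true(all(abs(off) < 5 * se))
  expect_equal(diag(CW), rep(1, nch), tolerance = 5 * se * sqrt(2))

  expect_error(simulateNoiseCovariance(sys$arr, sys$lf, 0, 0.2, 250, 0, 1),
               "nTrials")
  expect_error(simulateNoiseCovariance(sys$arr, sys$lf, 5, 0.001, 100, 0, 1),
               "sample")
})

test_that("generators are pure functions of seed and parameters", {
  sys <- smallStudySystem(seed = 31, nMag = 8, nsrc = 20)
  n1 <- simulateNoiseCovariance(sys$arr, sys$lf, 5, 0.2, 50, 0.5, seed = 4)
  n2 <- simulateNoiseCovariance(sys$arr, sys$lf, 5, 0.2, 50, 0.5, seed = 4)
  expect_identical(getMatrix(n1), getMatrix(n2))
  # and they do not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123)
  invisible(simulateNoiseCovariance(sys$arr, sys$lf, 3, 0.2, 50, 0, seed = 8))
  expect_identical(rnorm(1), before)
})
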