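Package: megres
Title: Resolution Analysis of Noise-Normalized Minimum-Norm MEG Source Estimates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation framework for evaluating the spatial resolution of
    linear distributed MEG source estimators. Generates synthetic cohorts of
    subjects (helmet sensor arrays of magnetometers and planar gradiometers,
    folded cortical source spaces, trial-structured baseline noise
    covariances), computes analytic spherical-conductor leadfields, builds
    minimum-norm (MNE) inverse operators and their dSPM and sLORETA
    noise-normalized variants, and evaluates point-spread and cross-talk
    functions of the resolution matrix with dipole localization error,
    spatial dispersion and overall amplitude metrics, including group-level
    difference maps and paired t-test statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, grDevices, yaml, jsonlite
Suggests: testthat (>= 3.0.0), MASS, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
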