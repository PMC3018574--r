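---
title: "Resolution analysis of noise-normalized minimum-norm MEG estimators"
author: "megres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolution analysis of noise-normalized minimum-norm MEG estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megres)
```

## The problem

Distributed MEG source estimation solves the underdetermined linear system
$\mathbf{d} = \mathbf{L}\,\mathbf{j}$, where $\mathbf{d}$ holds the sensor
measurements, $\mathbf{L}$ is the leadfield (forward) matrix and
$\mathbf{j}$ the source current distribution. A linear estimator is a
matrix $\mathbf{G}$ with $\hat{\mathbf{j}} = \mathbf{G}\mathbf{d}$, and
its spatial behaviour is completely captured by the resolution matrix

$$\mathbf{R} = \mathbf{G}\,\mathbf{L}, \qquad
\hat{\mathbf{j}} = \mathbf{R}\,\mathbf{j}.$$

Columns of $\mathbf{R}$ are point-spread functions (PSFs): how a unit
point source appears in the estimate. Rows are cross-talk functions
(CTFs): how every source leaks into the estimate at one location. megres
builds the classical $\ell_2$ minimum-norm estimator

$$\mathbf{G}_{\mathrm{MNE}} =
  \mathbf{L}^\top\!\left(\mathbf{L}\mathbf{L}^\top + \lambda\mathbf{C}\right)^{-1}$$

(with noise covariance $\mathbf{C}$ and regularization $\lambda$) and its
two standard noise-normalized variants, which rescale the rows of
$\mathbf{G}_{\mathrm{MNE}}$ by a diagonal weight matrix $\mathbf{W}$:

* **dSPM**: $W_{ii}^{-2} = [\mathbf{G}(\mathbf{C}/n_{\mathrm{av}})\mathbf{G}^\top]_{ii}$,
  the minimum-norm estimate of the noise variance at source $i$ after
  averaging $n_{\mathrm{av}}$ trials;
* **sLORETA**: $W_{ii}^{-2} = [\mathbf{G}\mathbf{L}]_{ii}$, the diagonal
  of the MNE resolution matrix.

Three structural facts drive the whole analysis, and all three are
asserted by the test suite:

1. $\mathbf{R}_{\mathrm{MNE}} = \mathbf{L}^\top(\mathbf{L}\mathbf{L}^\top+\lambda\mathbf{C})^{-1}\mathbf{L}$
   is symmetric, so MNE PSFs equal MNE CTFs.
2. Row scaling changes PSF *shapes* but only CTF *amplitudes*: localization
   error and dispersion of CTFs are identical for MNE, dSPM and sLORETA.
3. sLORETA PSFs peak exactly at the true source (zero dipole localization
   error): $|R_{ji}|/\sqrt{R_{jj}} \le \sqrt{R_{ii}}$ is Cauchy–Schwarz in
   the inner product induced by $(\mathbf{L}\mathbf{L}^\top+\lambda\mathbf{C})^{-1}$,
   with equality only at $j$ with leadfield parallel to $i$'s.

Each PSF/CTF is summarized by three per-source metrics: **DLE** (cm), the
distance between the peak of $|F|$ and the true source; **SD**
(sqrt-cm), $\sqrt{\sum_j d_{ij}F_j^2 / \sum_j F_j^2}$, the
amplitude-weighted spread around the true source; and **OA**,
$\sum_j |F_j|$, normalized per subject to its maximum before averaging so
that only relative amplitudes across locations are compared.

## The synthetic cohort

Real resolution studies use individual head geometries, sensor positions
and measured baseline covariances. megres replaces these inputs with a
generator whose defaults mirror such a study's configuration:

| parameter | default | meaning |
|---|---|---|
| `n_mag`, `n_grad` | 102, 204 | 306-channel helmet: magnetometers plus co-located orthogonal planar-gradiometer pairs |
| `helmet_radius` | 0.12 m | sensor shell radius |
| `conductor_radius` | 0.09 m | spherical conductor ("head") |
| `scalp_margin` | 0.01 m | gap between conductor surface and shallowest source |
| `n_sources` | 10000 | dipoles on the folded shell |
| `fold_depth`, `fold_frequency` | 0.03 m, 6 | gyrus/sulcus-like radial folding |
| `n_subjects` | 17 | cohort size |
| `jitter_scale` | 0.002 m | per-vertex anatomical jitter; also scales the rigid head-position rotation (angle SD `jitter_scale / conductor_radius`) |
| `n_trials`, `baseline_duration` | 146, 0.2 s | trial-structured baseline noise |
| `sampling_rate` | 250 Hz | gives 50 baseline samples/trial, 7300 in total — comfortably more than 306 channels, so the sample covariance can be full rank |
| `brain_noise_fraction` | 0.5 | share of noise variance routed through the leadfield |
| `snr` | 3 | regularization target |
| `n_averages` | 100 | covariance divisor for dSPM |

The source shell is
$r(\theta,\phi) = r_0 - f_d\,(1+\sin k\theta\,\sin k\phi)/2$ with
$r_0 = $ `conductor_radius - scalp_margin`; orientations are the exact
outward surface normals of that shell, so dipoles are perpendicular to the
synthetic "cortex" and no depth weighting is applied anywhere. The scalp
margin (1 cm, roughly the scalp-to-cortex distance at this head scale)
keeps every source strictly inside the conductor even after the default
2 mm Gaussian vertex jitter; the depth field is the radial distance below
the conductor surface.

Baseline noise is a mixture of i.i.d. white sensor noise and random
source activity projected through the leadfield, rescaled so the average
channel variance is independent of the mixing fraction; with fraction 0
the covariance converges to a scaled identity. The sampling rate and
filter properties of real baseline data are not modelled — both are
exposed as parameters rather than fixed guesses.

What the generator does **not** emulate: realistic cortical geometry
(sulcal walls facing each other, variable curvature), the BEM/real-conductor
field (a homogeneous sphere is used, which is analytic and radius- and
conductivity-independent), channel-specific noise spectra, and
environmental artefacts. Passing tests therefore demonstrate the
*estimator-level* properties — which are geometry-independent theorems —
and the *qualitative* depth/superficial patterns, not quantitative maps
for any real head.

## Numerical choices

* **Regularization.** $\lambda = \mathrm{tr}(\mathbf{L}\mathbf{L}^\top)/(\mathrm{tr}(\mathbf{C})\,\mathrm{snr}^2)$:
  the scaled noise term then carries $1/\mathrm{snr}^2$ of the average
  signal power. This is a whitening-free transcription of the usual
  $\lambda \propto 1/\mathrm{SNR}^2$ convention; $\lambda$ can always be
  passed explicitly. The covariance is *not* rescaled by `n_averages`
  when building $\mathbf{G}$ — that divisor enters only the dSPM weights
  (the documented alternative would rescale both).
* **Solver.** $\mathbf{G}$ is computed through a Cholesky factorization of
  $\mathbf{L}\mathbf{L}^\top + \lambda\mathbf{C}$; if the factorization
  fails, one round of diagonal loading ($10^{-10}\times$ mean diagonal) is
  applied and logged, and the condition number is reported.
* **Resolution matrix.** Built column-by-column through the same
  matrix-vector product as `applyInverse()`, so each column is
  bit-identical to the operator applied to the corresponding leadfield
  column. Dense $n\times n$ storage; `max_sources` (default 4000) caps the
  size and must be raised explicitly for larger runs.
* **Metrics.** Peaks use $|F|$ with ties broken toward the lowest index
  (deterministic; ties are reported). Distances are 3-D Euclidean, not
  geodesic along the folded shell — a documented extension point. SD
  weights use $F^2$; the exponent is a parameter (`sdExponent`, 1 or 2)
  because amplitude-weighting conventions differ between studies.
* **Degenerate group vertices.** Contrasts that are identically zero by
  theory (e.g. CTF-mode DLE between methods) have zero variance across
  subjects; the paired t map assigns $p = 1$ when the mean difference is
  also zero and $p = 0$ otherwise, flags the vertex, and never produces
  NaN. No multiple-comparison correction is applied (maps are displayed
  at uncorrected $p < 0.05$).
* **Determinism.** Every generator is a pure function of its seed; a
  master seed fans out as
  `child = (master mod 1e5) * 1e4 + subject * 10 + stage`, so adding a
  subject never perturbs existing subjects' draws, and two runs of
  `runStudy()` with the same configuration are byte-identical (TSVs print
  17 significant digits).

## Problem sizes

The packaged checks run the full chain on a 17-subject cohort at 500
sources and single systems at 300–1000 sources with the full 306-channel
array — sizes chosen so the dense resolution matrices ($n^2$ doubles per
subject) stay small while the Spearman depth correlations and
superficial-vertex comparisons are well powered. The estimator-level
theorems (symmetry, CTF invariance, zero sLORETA DLE) hold at any size;
the qualitative cohort findings were checked at these scales only.

## A minimal run

```{r example, eval = FALSE}
cfg <- defaultStudyConfig()
cfg$n_sources <- 500L
cfg$n_subjects <- 5L
cfg$output_dir <- tempfile("study")
res <- runStudy(cfg)
res$summary
```

## Known limitations

* Spherical conductor only: no EEG forward model (a sphere makes radial
  sources silent, which a realistic conductor would not exactly do), no
  BEM/FEM.
* Fixed source orientations; no loose/free orientation models, no
  beamformers, no depth weighting.
* 3-D Euclidean metric distances; geodesic distances along the folded
  surface are not implemented.
* The whitening-free $\lambda$ convention means absolute metric values
  depend on the (synthetic) noise scale; comparisons *between* methods on
  the same system — the object of the analysis — do not.
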