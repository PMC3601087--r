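---
title: "Grey-matter trajectory analysis: methods and design notes"
author: "vbmtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grey-matter trajectory analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical model the package implements, the
assumptions behind it, the tunable parameters and their defaults, what
the synthetic phantom does and does not emulate, and the numerical and
design choices made where more than one convention was defensible.

## The model

The response at each voxel is modulated grey matter: a tissue
partial-volume estimate multiplied by the Jacobian of the nonlinear
warp to a common space, then smoothed with an isotropic Gaussian kernel
(sigma = 2 mm, about 4.7 mm FWHM; `sigmaToFWHM()` implements
FWHM = 2*sqrt(2*ln 2)*sigma). For the user (CD) group, each in-mask
voxel is modelled as

    gm = b0 + b1*abstinence_weeks + b2*years_use + b3*age + e

with age a nuisance covariate, since years of use would otherwise proxy
for normal age-related GM decline. The fit is the Huber M-estimator:
least squares for residuals within `k` robust standard deviations,
linear loss beyond, solved by iteratively reweighted least squares.
Robustness matters here because modulated GM values at single voxels
are heavy-tailed across subjects (registration imperfections, vascular
and CSF partial-volume contamination).

Voxelwise t maps (t = b/se, df = n − p, i.e. 39 for 43 subjects and 4
columns) are split by coefficient sign so that increases and decreases
with each covariate are inferred separately. Significance requires both
a voxelwise two-tailed threshold (default p = 0.005, giving |t| >=
2.9756 at df 39) and membership in a sufficiently large connected
cluster, with the minimum size calibrated by Monte-Carlo simulation so
the family-wise probability of any chance cluster is at most alpha.

For each surviving cluster, the per-subject mean GM inside the cluster
is the ROI series. A robust line against the cluster's covariate is
fitted for the CD group, and the crossover point solves
`intercept + slope*x = control_mean`, where the control reference is
the arithmetic mean of control ROI values. Welch tests then compare CD
subjects strictly beyond the crossover with controls, and cross-term
checks ask whether a cluster found under one covariate also tracks the
other (uncorrected p < 0.05 in both cases, matching the convention of
the analyses this package reproduces).

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| Huber `k` | 1.345 | robust SDs | 95% Gaussian efficiency; the conventional choice |
| residual scale | MAD/0.6745 | GM-units | recomputed every IRLS iteration; consistent for Gaussian noise |
| scale floor | 1e-12*(1+\|median(y)\|) | GM-units | keeps exact-fit voxels (zero residuals) at weights 1 |
| IRLS tolerance | 1e-8 relative coefficient change | — | well below any scientific resolution; max 50 iterations, non-convergence flagged per voxel, voxel retained |
| voxelwise p | 0.005 two-tailed | — | cluster-forming threshold |
| df | n − p | — | fixed by the design; robust effective dfs are debated, and the t(39) convention pins this choice |
| connectivity | 6 (faces) | — | conservative cluster definition; 18/26 exposed |
| alpha (FWE) | 0.05 | — | family-wise error target |
| Monte-Carlo iterations | 10,000 production; 250–1,000 in tests | — | extent-threshold precision vs runtime |
| smoothness FWHM | 4.7 mm | mm | set equal to the data-smoothing kernel; residual smoothness is not estimated |
| mask rule | mean GM > 0.05 | GM-units | excludes background on phantoms; a package choice, exposed |
| voxel size | 2 mm isotropic | mm | 360 ul = 45 voxels; the acquisition-to-analysis grid is a config parameter |
| crossover window | [0, Inf) | covariate units | negative crossovers are reported but flagged implausible |

## The synthetic phantom

`cohortConfig()` defaults define the study conditions the package is
validated under: 43 CD + 43 control subjects; CD covariates uniform
over abstinence 1–102 weeks and 0.3–24 years of use; ages uniform over
20–55 for both groups; a 40×48×40 grid of 2 mm voxels whose support is
a centred ellipsoid (semi-axes 80% of the half-extent); baseline GM
0.5; white Gaussian subject noise (sd 0.03) smoothed with the sigma =
2 mm data kernel and added before clipping at zero, so the noise field
has the same spatial autocorrelation the Monte-Carlo null assumes.

Effects are spheres in which CD subjects' GM equals
`baseline + offset + slope*covariate`. The generative model needs the
`offset` term: with slope alone, every CD trajectory would pass through
the control baseline at covariate 0 and the crossover would always be
zero. The canonical validation effect (`abstinenceRecoveryEffect()`)
uses slope 0.002 GM-units/week and offset −0.07, i.e. a deficit at
early abstinence that crosses the control mean at 35 weeks — the
deficit-then-recovery trajectory the pipeline exists to detect.

Uniform covariate sampling is the least-committal reading of a reported
min–max range; it will not reproduce a reported mean ± SEM, which is
documented rather than asserted. The phantom deliberately emulates only
what the statistics consume: it has no anatomy, no tissue boundaries,
no registration error, and its noise is stationary and Gaussian.
Passing recovery tests therefore demonstrates correctness of the
estimators and calibration of the cluster inference under the stated
assumptions — not robustness to the non-stationary, anatomy-locked
noise of real VBM data.

## Numerical choices

- **Scale and SEs match the classic M-estimation conventions** (MAD
  about zero; standard errors from Huber's small-sample-corrected
  formula `sqrt(S)*kappa/mn` on the unweighted `(X'X)^{-1}`), which are
  also the defaults of the widely used `MASS::rlm`/`summary.rlm`
  ("XtX") implementation. The test suite exploits this: our IRLS and
  that independent implementation must agree to 1e-6 on random
  problems. With n = 4 points and one gross outlier the MAD scale can
  be so large that nothing is downweighted and the Huber fit equals
  least squares; this is a property of the estimator, shared by the
  reference implementation, not an implementation artifact.
- **Null fields are thresholded at Gaussian quantiles**, while data t
  maps use Student quantiles: the simulated fields are Gaussian by
  construction, and this is the long-standing Monte-Carlo
  cluster-simulation convention.
- **Extent-threshold tie-break:** the threshold is the smallest size
  whose null exceedance probability is strictly below alpha; survival
  requires cluster size >= threshold. With 100 null maxima uniform on
  1..100 and alpha 0.05 the threshold is 97.
- **Smoothing** is separable convolution with zero padding, kernel
  truncated at 4 sigma and renormalized to unit sum. Zero padding
  slightly deflates noise variance near the grid edge; variance checks
  in the tests therefore use interior voxels.
- **Degenerate inputs:** zero-variance responses return zero slopes
  with the intercept at the constant; zero slopes make the crossover
  invalid rather than raising; constant covariates make cross-term
  checks "not testable"; Welch tests on two constant equal groups
  return t = 0.
- **Geometry:** voxel indices are 0-based internally; all mm
  coordinates come from the affine (RAS+ as stored). Cluster
  centre-of-mass is the unweighted mean of member voxel centres mapped
  through the affine. Coordinate tables following the LPI display
  convention are numerically identical (left/posterior/inferior
  negative), so no flip is applied.
- **Determinism:** one global seed derives stage seeds (cohort = seed+1,
  null simulation = seed+2), so full runs are bit-reproducible and
  stages can be re-run in isolation. Voxelwise results are invariant to
  subject permutation up to floating-point summation order (about 1e-7
  on t values at default tolerances), not bitwise.

## Design decisions

- Per-ROI trends are single-predictor robust fits (one line per
  covariate per ROI), since each cluster is reported under exactly one
  term; a joint fit is available by passing nuisance covariates, whose
  coefficients are absorbed at their sample means so the reported
  intercept stays comparable to the control mean. Whether per-ROI fits
  should include age is genuinely open; the default excludes it, and
  `roiNuisance = "age"` enables it.
- "Beyond the crossover" means strictly greater covariate value.
- The gender comparison is implemented as the Yates-corrected
  chi-square for a 2×2 table, which is the standard two-proportion
  check (`binomial proportion test` is an alias in common usage).
- The analysis mask rule (mean GM across subjects above a threshold)
  is deliberately simple; real studies often intersect a template
  mask, which the reader can emulate by passing any logical array.

## Problem sizes used in validation

The shipped tests run phantom cohorts at 20–43 subjects per group on
16×18×16 to 40×48×40 grids, Monte-Carlo nulls at 100–1,000 iterations,
and the family-wise-error calibration at 1,000 calibration plus 400
evaluation iterations on the full 40×48×40 ellipsoid; these sizes give
stable pass/fail behaviour at interactive runtimes. The effect-recovery
study uses 20 independently seeded cohorts at the full study scale.

## Known limitations

- ROI trend fits reuse the voxels that were selected for significance,
  which inflates apparent effect sizes (selection circularity); the
  crossover abscissa is less affected than the correlation magnitude,
  but no correction is applied.
- The Monte-Carlo null assumes stationary Gaussian smoothness equal to
  the applied kernel; residual-based smoothness estimation is not
  implemented.
- Covariate measurement error (self-reported use and abstinence) is not
  modelled.
- The pipeline is cross-sectional: a crossover describes the fitted
  trend across subjects, not within-subject recovery.
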