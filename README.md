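# vbmtraj

Grey-matter trajectory analysis for voxel-based morphometry (VBM).

Cross-sectional studies of recovery from stimulant dependence ask how
regional grey-matter (GM) volume relates to how long someone used and
how long they have been abstinent. `vbmtraj` implements the complete
statistical pipeline for that question, operating on modulated, smoothed
GM maps (the standard output of VBM preprocessing):

1. **Voxelwise Huber robust regression.** At each voxel in the analysis
   mask, GM of the user group is modelled as

   `gm_i = b0 + b1 * abstinence_weeks_i + b2 * years_use_i + b3 * age_i + e_i`

   fitted by the Huber M-estimator (IRLS, tuning constant k = 1.345,
   MAD residual scale), with t = b/se at df = n − p. Coefficient and t
   maps are split by coefficient sign.
2. **Cluster-extent family-wise-error control.** Voxels pass a
   two-tailed |t| threshold (e.g. t(39) = 2.97 at p = 0.005) and must
   belong to a connected cluster at least as large as an extent
   threshold calibrated by Monte-Carlo simulation of smooth Gaussian
   null fields on the mask, so that a chance cluster survives with
   probability at most alpha (0.05).
3. **Trajectory crossover.** For each surviving cluster, per-subject
   mean GM is extracted for users and controls, a robust line is fitted
   against the covariate for users, and the crossover point — the
   covariate value where that line meets the control-group mean — is
   solved from `intercept + slope * x = control_mean`, followed by
   Welch tests of users beyond the crossover versus controls and
   cross-term independence checks.

Because real cohorts of this kind are rarely shareable, the package
includes a first-class synthetic phantom generator: ellipsoidal-support
GM maps with smoothed Gaussian noise and spherical regions whose GM is
linearly linked to a chosen covariate, plus ground-truth masks, so every
stage can be validated end to end against known answers.

## Worked example

Simulate a study-scale phantom (43 users + 43 controls on a 40×48×40
grid of 2 mm voxels) carrying one abstinence-linked sphere whose GM
starts 0.07 units below baseline and rises 0.002 units/week — a
deficit that crosses the control mean at 35 weeks — then run the whole
pipeline:

```r
library(vbmtraj)

cfg <- runConfig(
  cohort  = cohortConfig(effects = list(abstinenceRecoveryEffect())),
  cluster = clusterParams(nIterations = 1000),
  seed    = 42)
res <- runFullAnalysis(cfg)

res$tCrit                      # 2.9756  (p = 0.005 two-tailed, df 39)
res$extent$thresholdUL         # 184 ul  (23 voxels, Monte-Carlo, alpha 0.05)
res$clusters
#>               term polarity size_voxels volume_ul com_x com_y com_z peak_t
#> 1 abstinence_weeks positive         257      2056   -13     9     3   98.5
res$crossovers[, c("slope", "intercept", "control_mean", "crossover", "welch_p")]
#>   slope intercept control_mean crossover  welch_p
#> 1 0.002      0.43          0.5      35.2 1.44e-08
```

One cluster survives, its recovered slope (0.002 GM-units/week) and
crossover (35.2 weeks against the generating 35) match the embedded
effect, and users abstinent longer than the crossover have higher GM
than controls (Welch p = 1.4e-08).

Closed-form demographic utilities work directly from printed group
summaries:

```r
welchTFromSummary(groupSummary(37.5, 1.2, 43),   # users:    mean, SEM, n
                  groupSummary(38.7, 1.6, 43))   # controls
#> -0.6

rc <- referenceClusters()   # shipped reference cluster table
summarizeCrossovers(rc$crossover[rc$term == "abstinence_weeks" &
                                 rc$polarity == "positive"])
#> $n 8   $mean 35.5875   $sd 6.206549   $min 26.4   $max 44.9
```

## Package layout

- `R/synthCohort.R` — phantom cohorts with known effects
- `R/volumeIO.R` — NIfTI I/O, geometry, masks, Gaussian smoothing
- `R/robustGLM.R` — Huber IRLS (C++ core), voxelwise fits, sign split
- `R/clusterMC.R` — 3D labeling, Monte-Carlo null, extent threshold
- `R/roiCrossover.R` — ROI means, trends, crossovers, Welch/cross-term
- `R/summaryStats.R` — Welch/Satterthwaite/chi-square/correlation/FWHM
- `R/pipeline.R` — orchestration and report writing
- `vignettes/grey-matter-trajectories.Rmd` — methods and design notes
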