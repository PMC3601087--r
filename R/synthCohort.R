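#' Specify a ground-truth regional effect
#'
#' An effect is a sphere inside the phantom support where CD subjects'
#' grey matter departs from the control baseline as a linear function of
#' one covariate: \code{offset + slope * covariate}. The offset shifts
#' the CD group as a whole, so the covariate value at which the CD trend
#' meets the control baseline is \code{-offset/slope} -- the ground-truth
#' crossover point. Controls are never touched by effects.
#'
#' @param center 1-based voxel index triple, sphere centre.
#' @param radiusMM sphere radius in mm.
#' @param term covariate driving the effect: \code{"abstinence_weeks"},
#'   \code{"years_use"} or \code{"age"}.
#' @param slope GM-units per covariate unit.
#' @param offset GM-units added to CD subjects in the sphere (default 0).
#' @return A list of class \code{"EffectSpec"}.
#' @examples
#' # recovery-like trajectory: deficit at short abstinence, crossing the
#' # control baseline at 35 weeks
#' effectSpec(c(14, 30, 24), radiusMM = 8, term = "abstinence_weeks",
#'            slope = 0.002, offset = -0.07)
#' @export
effectSpec <- function(center, radiusMM, term, slope, offset = 0) {
  term <- match.arg(term, c("abstinence_weeks", "years_use", "age"))
  if (radiusMM <= 0) stop("radiusMM must be > 0")
  if (length(center) != 3L) stop("center must be a voxel index triple")
  structure(list(center = as.numeric(center), radiusMM = radiusMM,
                 term = term, slope = slope, offset = offset),
            class = "EffectSpec")
}

#' Configure a phantom cohort
#'
#' Defaults mirror the study conditions the package models: 43 abstinent
#' cocaine-dependent (CD) users and 43 controls; CD covariates sampled
#' uniformly over abstinence 1--102 weeks and 0.3--24 years of use; ages
#' 20--55 for everyone; maps smoothed with a sigma = 2 mm Gaussian
#' (about 4.7 mm FWHM) on a 40x48x40 grid of 2 mm voxels, where the
#' 360 ul cluster-extent convention equals 45 voxels.
#'
#' @param nCD number of CD subjects.
#' @param nControl number of control subjects.
#' @param gridDim grid dimensions (integer triple).
#' @param voxelSizeMM voxel size in mm.
#' @param baselineGM baseline modulated GM value inside the support.
#' @param noiseSD standard deviation of the white Gaussian subject noise
#'   before smoothing (GM-units).
#' @param smoothSigmaMM Gaussian sigma applied to the noise, matching
#'   the data-smoothing kernel.
#' @param covariateRanges named list of (min, max) sampling ranges.
#' @param effects list of \code{\link{effectSpec}} objects.
#' @param seed integer seed; the whole cohort is bit-reproducible.
#' @return A list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(nCD = 43, nControl = 43,
                         gridDim = c(40, 48, 40),
                         voxelSizeMM = c(2, 2, 2),
                         baselineGM = 0.5,
                         noiseSD = 0.03,
                         smoothSigmaMM = 2,
                         covariateRanges = list(
                           abstinence_weeks = c(1, 102),
                           years_use = c(0.3, 24),
                           age = c(20, 55)),
                         effects = list(),
                         seed = 1L) {
  if (nCD <= 0 || nControl <= 0) stop("subject counts must be positive")
  if (noiseSD < 0) stop("noiseSD must be >= 0")
  for (nm in c("abstinence_weeks", "years_use", "age")) {
    rg <- covariateRanges[[nm]]
    if (is.null(rg)) stop("missing covariate range: ", nm)
    if (diff(rg) <= 0) stop("degenerate or inverted range for ", nm)
  }
  if (length(effects) && inherits(effects, "EffectSpec"))
    effects <- list(effects)
  for (e in effects)
    if (!inherits(e, "EffectSpec")) stop("effects must be EffectSpec objects")
  structure(list(nCD = as.integer(nCD), nControl = as.integer(nControl),
                 gridDim = as.integer(gridDim),
                 voxelSizeMM = rep_len(as.numeric(voxelSizeMM), 3L),
                 baselineGM = baselineGM, noiseSD = noiseSD,
                 smoothSigmaMM = smoothSigmaMM,
                 covariateRanges = covariateRanges,
                 effects = effects, seed = as.integer(seed)),
            class = "CohortConfig")
}

#' The package's canonical validation effect
#'
#' One abstinence-linked sphere (radius 8 mm) with slope 0.002 GM-units
#' per week and a CD offset of -0.07 GM-units, so the CD trajectory
#' starts below the control baseline and crosses it at 35 weeks of
#' abstinence -- the deficit-then-recovery pattern the pipeline is
#' designed to detect.
#'
#' @param gridDim grid dimensions the sphere must fit inside.
#' @return An \code{\link{effectSpec}}.
#' @export
abstinenceRecoveryEffect <- function(gridDim = c(40, 48, 40)) {
  effectSpec(center = round(gridDim * c(0.35, 0.6, 0.55)),
             radiusMM = 8, term = "abstinence_weeks",
             slope = 0.002, offset = -0.07)
}

#' Sample the covariate table for a phantom cohort
#'
#' Controls come first, then CD subjects. Ages are uniform over the
#' configured range for both groups; abstinence and years of use are
#' uniform over their ranges for CD subjects and NA for controls
#' (uniform sampling is the least-committal emulation of a reported
#' min--max range).
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return data.frame with columns subject, group, age,
#'   abstinence_weeks, years_use.
#' @export
generateCovariates <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  rg <- config$covariateRanges
  .withSeed(config$seed, {
    nC <- config$nControl
    nD <- config$nCD
    n <- nC + nD
    out <- data.frame(
      subject = c(sprintf("ctrl%03d", seq_len(nC)),
                  sprintf("cd%03d", seq_len(nD))),
      group = c(rep("control", nC), rep("CD", nD)),
      age = runif(n, rg$age[1], rg$age[2]),
      abstinence_weeks = NA_real_,
      years_use = NA_real_,
      stringsAsFactors = FALSE)
    cd <- out$group == "CD"
    out$abstinence_weeks[cd] <- runif(nD, rg$abstinence_weeks[1],
                                      rg$abstinence_weeks[2])
    out$years_use[cd] <- runif(nD, rg$years_use[1], rg$years_use[2])
    out
  })
}

# logical sphere on the grid, radius in mm around a 1-based voxel centre
.sphereMask <- function(grid, center, radiusMM) {
  idx <- arrayInd(seq_len(prod(grid@dim)), grid@dim)
  mm <- voxelToWorld(grid, idx - 1)
  cmm <- voxelToWorld(grid, matrix(center - 1, nrow = 1))
  d2 <- (mm[, 1] - cmm[1])^2 + (mm[, 2] - cmm[2])^2 + (mm[, 3] - cmm[3])^2
  array(d2 <= radiusMM^2, dim = grid@dim)
}

#' Generate phantom grey-matter maps
#'
#' Each subject map is \code{baseline + smoothed noise} inside an
#' ellipsoidal support (zero outside, clipped at zero); CD subjects
#' additionally receive \code{offset + slope * covariate} inside every
#' effect sphere. Noise is white Gaussian smoothed with the data kernel,
#' emulating the output of VBM preprocessing (registered, modulated,
#' smoothed maps). Ground-truth effect masks ride along in the result.
#'
#' @param covariates table from \code{\link{generateCovariates}}.
#' @param config the matching \code{\link{cohortConfig}}.
#' @return A \linkS4class{GMCohort}.
#' @export
generateGMMaps <- function(covariates, config) {
  stopifnot(inherits(config, "CohortConfig"))
  grid <- voxelGrid(config$gridDim, config$voxelSizeMM)
  support <- .ellipsoidMask(grid@dim)
  effMasks <- list()
  for (i in seq_along(config$effects)) {
    e <- config$effects[[i]]
    sph <- .sphereMask(grid, e$center, e$radiusMM)
    if (!any(sph)) stop("effect sphere ", i, " contains no voxels")
    if (any(sph & !support))
      stop("effect sphere ", i, " extends outside the phantom support")
    effMasks[[sprintf("%s_%d", e$term, i)]] <- sph
  }
  n <- nrow(covariates)
  maps <- array(0, dim = c(grid@dim, n))
  sigVox <- config$smoothSigmaMM / grid@voxelSize
  .withSeed(config$seed + 1L, {
    for (s in seq_len(n)) {
      vol <- array(config$baselineGM, dim = grid@dim)
      if (config$noiseSD > 0) {
        noise <- array(rnorm(prod(grid@dim), sd = config$noiseSD),
                       dim = grid@dim)
        vol <- vol + .gaussianSmooth3dCpp(noise, grid@dim, sigVox)
      }
      if (covariates$group[s] == "CD") {
        for (i in seq_along(config$effects)) {
          e <- config$effects[[i]]
          cov <- covariates[[e$term]][s]
          sph <- effMasks[[sprintf("%s_%d", e$term, i)]]
          vol[sph] <- vol[sph] + e$offset + e$slope * cov
        }
      }
      vol[!support] <- 0
      vol[vol < 0] <- 0
      maps[, , , s] <- vol
    }
  })
  new("GMCohort", maps = maps, covariates = covariates, grid = grid,
      support = support, effectMasks = effMasks)
}

#' Simulate a complete phantom cohort
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return A \linkS4class{GMCohort}.
#' @export
simulateCohort <- function(config = cohortConfig()) {
  generateGMMaps(generateCovariates(config), config)
}

#' Write a cohort to disk
#'
#' One NIfTI per subject, the covariate CSV, ground-truth effect masks
#' (8-bit NIfTI) and a JSON manifest binding them together. The layout
#' round-trips bit-for-bit through \code{\link{readCohort}}.
#'
#' @param cohort a \linkS4class{GMCohort}.
#' @param dir output directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  cv <- cohort@covariates
  files <- file.path(dir, paste0(cv$subject, ".nii.gz"))
  for (s in seq_len(nrow(cv)))
    writeStatMap(cohort@maps[, , , s], cohort@grid, files[s])
  write.csv(cv, file.path(dir, "covariates.csv"), row.names = FALSE)
  writeStatMap(array(as.numeric(cohort@support), dim = cohort@grid@dim),
               cohort@grid, file.path(dir, "support.nii.gz"),
               datatype = "uint8")
  effFiles <- character(0)
  for (nm in names(cohort@effectMasks)) {
    f <- file.path(dir, paste0("effect_", nm, ".nii.gz"))
    writeStatMap(array(as.numeric(cohort@effectMasks[[nm]]),
                       dim = cohort@grid@dim),
                 cohort@grid, f, datatype = "uint8")
    effFiles[nm] <- basename(f)
  }
  manifest <- list(n_subjects = nrow(cv),
                   subjects = cv$subject,
                   maps = basename(files),
                   covariates = "covariates.csv",
                   support = "support.nii.gz",
                   effect_masks = as.list(effFiles),
                   grid = list(dim = cohort@grid@dim,
                               voxel_size_mm = cohort@grid@voxelSize))
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mf)
}

#' Read a cohort written by \code{\link{writeCohort}}
#'
#' @param dir directory containing the manifest.
#' @return A \linkS4class{GMCohort}.
#' @export
readCohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  cv <- read.csv(file.path(dir, manifest$covariates),
                 stringsAsFactors = FALSE)
  cv$abstinence_weeks <- as.numeric(cv$abstinence_weeks)
  cv$years_use <- as.numeric(cv$years_use)
  first <- readStatMap(file.path(dir, manifest$maps[1]))
  grid <- first$grid
  maps <- array(0, dim = c(grid@dim, nrow(cv)))
  maps[, , , 1] <- first$values
  for (s in seq_len(nrow(cv))[-1]) {
    vol <- readStatMap(file.path(dir, manifest$maps[s]))
    if (!.sameGrid(vol$grid, grid))
      stop("map ", manifest$maps[s], " disagrees with cohort grid")
    maps[, , , s] <- vol$values
  }
  support <- readStatMap(file.path(dir, manifest$support))$values > 0
  eff <- list()
  for (nm in names(manifest$effect_masks))
    eff[[nm]] <- readStatMap(
      file.path(dir, manifest$effect_masks[[nm]]))$values > 0
  new("GMCohort", maps = maps, covariates = cv, grid = grid,
      support = support, effectMasks = eff)
}
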