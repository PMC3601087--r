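#' Monte-Carlo cluster-correction parameters
#'
#' @param voxelP two-tailed uncorrected voxelwise p threshold.
#' @param df degrees of freedom for thresholding data t maps.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (full).
#' @param alphaFWE target family-wise error rate.
#' @param nIterations Monte-Carlo iterations (production default 10000;
#'   smaller values are fine for exploratory work).
#' @param smoothnessFWHM assumed spatial smoothness of the noise in mm
#'   FWHM; default matches the 4.7 mm data-smoothing kernel.
#' @param seed integer seed for the null simulation.
#' @return list of class \code{"ClusterParams"}.
#' @export
clusterParams <- function(voxelP = 0.005, df = 39L, connectivity = 6L,
                          alphaFWE = 0.05, nIterations = 10000L,
                          smoothnessFWHM = 4.7, seed = 1L) {
  if (voxelP <= 0 || voxelP >= 1) stop("voxelP must be in (0,1)")
  if (alphaFWE <= 0 || alphaFWE >= 1) stop("alphaFWE must be in (0,1)")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  if (nIterations < 1) stop("nIterations must be >= 1")
  if (smoothnessFWHM < 0) stop("smoothnessFWHM must be >= 0")
  structure(list(voxelP = voxelP, df = as.integer(df),
                 connectivity = as.integer(connectivity),
                 alphaFWE = alphaFWE, nIterations = as.integer(nIterations),
                 smoothnessFWHM = smoothnessFWHM, seed = as.integer(seed)),
            class = "ClusterParams")
}

#' Label connected components of a binary 3D grid
#'
#' @param x logical (or 0/1) 3D array.
#' @param connectivity 6, 18 or 26.
#' @return list with \code{labels} (integer array, background 0) and
#'   \code{sizes} (voxels per label).
#' @export
labelClusters <- function(x, connectivity = 6L) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop("grid must be binary")
    x <- array(x > 0, dim = dim(x))
  }
  .labelClustersCpp(x, as.integer(dim(x)), as.integer(connectivity))
}

#' Simulate the null distribution of the maximum cluster size
#'
#' Per iteration: a white Gaussian field on the grid is smoothed to the
#' assumed FWHM, standardized to unit variance within the mask, and
#' thresholded two-sided at the Gaussian quantile for \code{voxelP}
#' (null fields are Gaussian by construction, so Gaussian rather than
#' t quantiles are used -- the classic Monte-Carlo cluster-simulation
#' convention). Suprathreshold voxels are labeled per sign and the
#' maximum component size over both signs is recorded.
#'
#' @param mask an \linkS4class{AnalysisMask}.
#' @param params a \code{\link{clusterParams}}.
#' @return A \linkS4class{NullClusterDistribution}.
#' @export
simulateNullMaxClusters <- function(mask, params = clusterParams()) {
  stopifnot(is(mask, "AnalysisMask"), inherits(params, "ClusterParams"))
  grid <- mask@grid
  sigVox <- fwhmToSigma(params$smoothnessFWHM) / grid@voxelSize
  u <- qnorm(1 - params$voxelP / 2)
  msk <- mask@mask
  inMask <- which(msk)
  dims <- grid@dim
  maxSizes <- integer(params$nIterations)
  .withSeed(params$seed, {
    for (it in seq_len(params$nIterations)) {
      field <- array(rnorm(prod(dims)), dim = dims)
      if (any(sigVox > 0))
        field <- .gaussianSmooth3dCpp(field, dims, sigVox)
      v <- field[inMask]
      v <- (v - mean(v)) / sd(v)
      z <- array(0, dim = dims)
      z[inMask] <- v
      best <- 0L
      for (sgn in c(1, -1)) {
        supra <- array(sgn * z > u, dim = dims)
        supra[!msk] <- FALSE
        if (any(supra)) {
          sizes <- .labelClustersCpp(supra, dims, params$connectivity)$sizes
          best <- max(best, sizes)
        }
      }
      maxSizes[it] <- best
    }
  })
  new("NullClusterDistribution", maxSizes = maxSizes,
      params = c(unclass(params), list(voxelVolumeUL = voxelVolume(grid))))
}

#' Cluster-extent threshold from a null distribution
#'
#' The smallest cluster size whose null exceedance probability (fraction
#' of iterations whose maximum cluster reaches that size) falls below
#' \code{alpha}; clusters at least this large survive correction.
#'
#' @param dist a \linkS4class{NullClusterDistribution}.
#' @param alpha family-wise error rate (defaults to the simulated
#'   \code{alphaFWE}).
#' @return list: \code{thresholdVoxels}, \code{thresholdUL} (NA when the
#'   simulation grid's voxel volume is unknown), \code{alpha}.
#' @export
extentThreshold <- function(dist, alpha = NULL) {
  stopifnot(is(dist, "NullClusterDistribution"))
  if (is.null(alpha)) alpha <- dist@params$alphaFWE
  if (is.null(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0,1)")
  sizes <- dist@maxSizes
  for (s in seq_len(max(sizes) + 1L)) {
    if (mean(sizes >= s) < alpha) break
  }
  vv <- dist@params$voxelVolumeUL
  list(thresholdVoxels = s,
       thresholdUL = if (is.null(vv)) NA_real_ else s * vv,
       alpha = alpha)
}

#' Extract the surviving-cluster table for one term
#'
#' Thresholds the sign-split t maps at \code{tCrit}, labels connected
#' components, drops clusters smaller than \code{extentVoxels}, and
#' tabulates size, volume, centre of mass (unweighted mean of member
#' voxel centres, mapped through the affine) and the peak |t| with its
#' location. Surviving clusters are relabeled 1..K per polarity in
#' decreasing size order.
#'
#' @param statMaps a \linkS4class{StatMaps}.
#' @param term design column to tabulate.
#' @param tCrit voxelwise |t| threshold (see \code{\link{criticalT}}).
#' @param extentVoxels minimum surviving cluster size in voxels.
#' @param connectivity 6, 18 or 26.
#' @return A \linkS4class{ClusterTable} (possibly with an empty table).
#' @export
extractClusterTable <- function(statMaps, term, tCrit, extentVoxels,
                                connectivity = 6L) {
  stopifnot(is(statMaps, "StatMaps"))
  grid <- geometry(statMaps)
  halves <- splitBySign(statMaps, term)
  rows <- list()
  labsOut <- list(positive = array(0L, dim = grid@dim),
                  negative = array(0L, dim = grid@dim))
  for (pol in c("positive", "negative")) {
    tm <- halves[[pol]]
    supra <- array(!is.na(tm) & abs(tm) >= tCrit, dim = grid@dim)
    if (!any(supra)) next
    lab <- .labelClustersCpp(supra, grid@dim, as.integer(connectivity))
    keep <- which(lab$sizes >= extentVoxels)
    if (!length(keep)) next
    keep <- keep[order(lab$sizes[keep], decreasing = TRUE)]
    for (newId in seq_along(keep)) {
      old <- keep[newId]
      vox <- which(lab$labels == old)
      labsOut[[pol]][vox] <- newId
      ijk <- arrayInd(vox, grid@dim) - 1
      com <- voxelToWorld(grid, colMeans(ijk))
      tv <- tm[vox]
      pk <- which.max(abs(tv))
      pkmm <- voxelToWorld(grid, ijk[pk, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        term = term, polarity = pol, label = newId,
        size_voxels = length(vox),
        volume_ul = length(vox) * voxelVolume(grid),
        com_x = com[1], com_y = com[2], com_z = com[3],
        peak_t = tv[pk], peak_x = pkmm[1], peak_y = pkmm[2],
        peak_z = pkmm[3], stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(term = character(0), polarity = character(0),
                         label = integer(0), size_voxels = integer(0),
                         volume_ul = numeric(0), com_x = numeric(0),
                         com_y = numeric(0), com_z = numeric(0),
                         peak_t = numeric(0), peak_x = numeric(0),
                         peak_y = numeric(0), peak_z = numeric(0),
                         stringsAsFactors = FALSE)
  new("ClusterTable", table = tab, labels = labsOut, grid = grid,
      params = list(term = term, tCrit = tCrit,
                    extentVoxels = extentVoxels,
                    connectivity = as.integer(connectivity)))
}
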