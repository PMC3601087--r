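#' Voxel grid geometry
#'
#' Shared geometry for every volume in an analysis: grid dimensions,
#' voxel size in mm, and the affine mapping 0-based voxel indices to
#' world (mm, RAS+) coordinates. All world coordinates reported by the
#' package come from this affine; nothing is hand-flipped.
#'
#' @slot dim integer triple, grid extent per axis.
#' @slot voxelSize numeric triple, voxel edge length in mm.
#' @slot affine 4x4 matrix taking 0-based voxel indices to mm.
#' @export
setClass("VoxelGrid",
         representation(dim = "integer", voxelSize = "numeric",
                        affine = "matrix"))

setValidity("VoxelGrid", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 1L))
    return("dim must be a positive integer triple")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be a positive triple (mm)")
  if (!all(dim(object@affine) == c(4L, 4L)))
    return("affine must be a 4x4 matrix")
  if (max(abs(object@affine[4, ] - c(0, 0, 0, 1))) > 1e-8)
    return("affine last row must be (0,0,0,1)")
  TRUE
})

#' Construct a voxel grid
#'
#' When no affine is given, the grid is centred on the world origin with
#' axis-aligned RAS+ axes: \code{affine = diag(voxelSize)} plus a
#' translation placing the grid centre at 0 mm.
#'
#' @param dim integer triple of grid dimensions.
#' @param voxelSize voxel edge lengths in mm (scalar recycled to 3).
#' @param affine optional 4x4 voxel(0-based)-to-mm matrix.
#' @return A \linkS4class{VoxelGrid}.
#' @examples
#' g <- voxelGrid(c(40, 48, 40))
#' voxelVolume(g)  # 8 microlitres at 2 mm isotropic
#' @export
voxelGrid <- function(dim, voxelSize = c(2, 2, 2), affine = NULL) {
  dim <- as.integer(dim)
  voxelSize <- rep_len(as.numeric(voxelSize), 3L)
  if (is.null(affine)) {
    affine <- diag(c(voxelSize, 1))
    affine[1:3, 4] <- -(dim - 1) / 2 * voxelSize
  }
  new("VoxelGrid", dim = dim, voxelSize = voxelSize, affine = affine)
}

#' A single subject's modulated grey-matter map
#'
#' Non-negative modulated grey-matter values (partial volume times warp
#' Jacobian, unitless) on a common grid.
#'
#' @slot values non-negative 3D array.
#' @slot grid the \linkS4class{VoxelGrid} geometry.
#' @slot subjectID subject identifier.
#' @export
setClass("GMMap",
         representation(values = "array", grid = "VoxelGrid",
                        subjectID = "character"))

setValidity("GMMap", function(object) {
  if (!all(dim(object@values) == object@grid@dim))
    return("values dimensions do not match grid")
  v <- object@values
  if (any(!is.finite(v))) return("values must be finite")
  if (any(v < 0)) return("values must be non-negative")
  TRUE
})

#' A phantom or real cohort: maps plus covariates
#'
#' Binds the per-subject grey-matter volumes (4D array, subject last) to
#' the covariate table. For synthetic cohorts the ellipsoidal phantom
#' support and the ground-truth effect masks are carried along so that
#' recovery tests never have to re-derive them.
#'
#' @slot maps 4D array (x, y, z, subject) of modulated GM values.
#' @slot covariates data.frame with columns subject, group, age,
#'   abstinence_weeks, years_use (the last two are NA for controls).
#' @slot grid shared \linkS4class{VoxelGrid}.
#' @slot support logical 3D array, the phantom/brain support.
#' @slot effectMasks named list of logical 3D arrays marking where each
#'   ground-truth effect was inserted (empty for real data).
#' @export
setClass("GMCohort",
         representation(maps = "array", covariates = "data.frame",
                        grid = "VoxelGrid", support = "array",
                        effectMasks = "list"))

setValidity("GMCohort", function(object) {
  d <- dim(object@maps)
  if (length(d) != 4L) return("maps must be a 4D array")
  if (!all(d[1:3] == object@grid@dim))
    return("maps grid does not match geometry")
  cv <- object@covariates
  need <- c("subject", "group", "age", "abstinence_weeks", "years_use")
  if (!all(need %in% names(cv)))
    return(paste("covariates must contain:", paste(need, collapse = ", ")))
  if (nrow(cv) != d[4]) return("one covariate row per map required")
  if (anyDuplicated(cv$subject)) return("subject ids must be unique")
  if (!all(cv$group %in% c("control", "CD")))
    return("group must be 'control' or 'CD'")
  cd <- cv$group == "CD"
  if (any(is.na(cv$abstinence_weeks[cd])) || any(is.na(cv$years_use[cd])))
    return("CD subjects must have abstinence_weeks and years_use")
  if (any(!is.na(cv$abstinence_weeks[!cd])) || any(!is.na(cv$years_use[!cd])))
    return("controls must not carry CD-only covariates")
  if (!all(dim(object@support) == object@grid@dim))
    return("support grid mismatch")
  TRUE
})

#' Analysis mask
#'
#' The voxel domain over which the voxelwise model is fitted; outside it
#' every statistic map is NaN.
#'
#' @slot mask logical 3D array.
#' @slot grid the \linkS4class{VoxelGrid}.
#' @export
setClass("AnalysisMask",
         representation(mask = "array", grid = "VoxelGrid"))

setValidity("AnalysisMask", function(object) {
  if (!all(dim(object@mask) == object@grid@dim))
    return("mask dimensions do not match grid")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!any(object@mask)) return("empty mask")
  TRUE
})

#' Voxelwise regression statistic maps
#'
#' Per design column, the coefficient and t maps over the analysis mask
#' (NaN outside). Degrees of freedom are fixed at n - p.
#'
#' @slot beta named list of 3D arrays, one per design column.
#' @slot tstat named list of 3D arrays, one per design column.
#' @slot df residual degrees of freedom (n - p).
#' @slot mask the \linkS4class{AnalysisMask} used for fitting.
#' @slot info list of fit metadata (tuning constant, non-convergence
#'   count, subject ids).
#' @export
setClass("StatMaps",
         representation(beta = "list", tstat = "list", df = "integer",
                        mask = "AnalysisMask", info = "list"))

setValidity("StatMaps", function(object) {
  if (!identical(names(object@beta), names(object@tstat)))
    return("beta and tstat terms disagree")
  for (nm in names(object@beta)) {
    if (!all(dim(object@beta[[nm]]) == object@mask@grid@dim))
      return("map grid mismatch")
  }
  if (object@df < 1L) return("df must be >= 1")
  TRUE
})

#' Surviving-cluster table
#'
#' Clusters that pass both the voxelwise |t| threshold and the
#' Monte-Carlo-calibrated extent threshold, for one regression term,
#' split by coefficient sign. Volumes are in microlitres; centres of
#' mass are unweighted means of member voxel centres mapped through the
#' grid affine.
#'
#' @slot table data.frame: term, polarity, label, size_voxels,
#'   volume_ul, com_x/y/z, peak_t, peak_x/y/z.
#' @slot labels list with elements \code{positive} and \code{negative}:
#'   integer label arrays (0 outside surviving clusters).
#' @slot grid the \linkS4class{VoxelGrid}.
#' @slot params thresholds used (tCrit, extentVoxels, connectivity).
#' @export
setClass("ClusterTable",
         representation(table = "data.frame", labels = "list",
                        grid = "VoxelGrid", params = "list"))

#' Null distribution of maximum cluster size
#'
#' One maximum suprathreshold cluster size (pooled over both signs) per
#' Monte-Carlo iteration of a smooth Gaussian null field on the mask.
#'
#' @slot maxSizes integer vector, one entry per iteration.
#' @slot params the \code{\link{clusterParams}} used, plus the voxel
#'   volume of the simulation grid.
#' @export
setClass("NullClusterDistribution",
         representation(maxSizes = "integer", params = "list"))

setValidity("NullClusterDistribution", function(object) {
  if (length(object@maxSizes) < 1L) return("empty distribution")
  if (any(object@maxSizes < 0L)) return("sizes must be >= 0")
  TRUE
})
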