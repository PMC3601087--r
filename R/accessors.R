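#' @name accessors
#' @title Accessors for vbmtraj objects
#' @description Slot access for the package's S4 containers goes through
#'   these generics rather than \code{@}.
#' @param x an object.
#' @param ... passed to methods.
NULL

#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("affineMatrix", function(x) standardGeneric("affineMatrix"))
#' @rdname accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))
#' @rdname accessors
#' @export
setGeneric("maskVolume", function(x) standardGeneric("maskVolume"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("gmValues", function(x) standardGeneric("gmValues"))
#' @rdname accessors
#' @export
setGeneric("gmMaps", function(x) standardGeneric("gmMaps"))
#' @rdname accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))
#' @rdname accessors
#' @export
setGeneric("effectMasks", function(x) standardGeneric("effectMasks"))
#' @rdname accessors
#' @export
setGeneric("supportMask", function(x) standardGeneric("supportMask"))
#' @rdname accessors
#' @param term design column name.
#' @export
setGeneric("betaMap", function(x, term) standardGeneric("betaMap"))
#' @rdname accessors
#' @export
setGeneric("tMap", function(x, term) standardGeneric("tMap"))
#' @rdname accessors
#' @export
setGeneric("designTerms", function(x) standardGeneric("designTerms"))
#' @rdname accessors
#' @export
setGeneric("dfResidual", function(x) standardGeneric("dfResidual"))
#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @rdname accessors
#' @param polarity \code{"positive"} or \code{"negative"}.
#' @export
setGeneric("clusterLabels", function(x, polarity) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("maxClusterSizes", function(x) standardGeneric("maxClusterSizes"))

#' @rdname accessors
setMethod("geometry", "VoxelGrid", function(x) x)
#' @rdname accessors
setMethod("geometry", "GMMap", function(x) x@grid)
#' @rdname accessors
setMethod("geometry", "GMCohort", function(x) x@grid)
#' @rdname accessors
setMethod("geometry", "AnalysisMask", function(x) x@grid)
#' @rdname accessors
setMethod("geometry", "StatMaps", function(x) x@mask@grid)
#' @rdname accessors
setMethod("geometry", "ClusterTable", function(x) x@grid)

#' @rdname accessors
setMethod("voxelSize", "VoxelGrid", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "ANY", function(x) voxelSize(geometry(x)))
#' @rdname accessors
setMethod("affineMatrix", "VoxelGrid", function(x) x@affine)
#' @rdname accessors
setMethod("affineMatrix", "ANY", function(x) affineMatrix(geometry(x)))

#' @rdname accessors
setMethod("maskArray", "AnalysisMask", function(x) x@mask)
#' @rdname accessors
setMethod("nVoxels", "AnalysisMask", function(x) sum(x@mask))
#' @rdname accessors
setMethod("maskVolume", "AnalysisMask",
          function(x) sum(x@mask) * voxelVolume(x@grid))

#' @rdname accessors
setMethod("gmValues", "GMMap", function(x) x@values)
#' @rdname accessors
setMethod("gmMaps", "GMCohort", function(x) x@maps)
#' @rdname accessors
setMethod("covariates", "GMCohort", function(x) x@covariates)
#' @rdname accessors
setMethod("effectMasks", "GMCohort", function(x) x@effectMasks)
#' @rdname accessors
setMethod("supportMask", "GMCohort", function(x) x@support)

#' @rdname accessors
setMethod("betaMap", "StatMaps", function(x, term) {
  if (!term %in% names(x@beta)) stop("no such term: ", term)
  x@beta[[term]]
})
#' @rdname accessors
setMethod("tMap", "StatMaps", function(x, term) {
  if (!term %in% names(x@tstat)) stop("no such term: ", term)
  x@tstat[[term]]
})
#' @rdname accessors
setMethod("designTerms", "StatMaps", function(x) names(x@beta))
#' @rdname accessors
setMethod("dfResidual", "StatMaps", function(x) x@df)

#' @rdname accessors
setMethod("clusters", "ClusterTable", function(x) x@table)
#' @rdname accessors
setMethod("clusterLabels", "ClusterTable", function(x, polarity) {
  polarity <- match.arg(polarity, c("positive", "negative"))
  x@labels[[polarity]]
})
#' @rdname accessors
setMethod("maxClusterSizes", "NullClusterDistribution",
          function(x) x@maxSizes)

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid %s at %s mm (%.1f ul/voxel)\n",
              paste(object@dim, collapse = "x"),
              paste(format(object@voxelSize), collapse = "x"),
              voxelVolume(object)))
})

setMethod("show", "GMCohort", function(object) {
  cv <- object@covariates
  cat(sprintf("GMCohort: %d subjects (%d CD, %d control) on %s grid\n",
              nrow(cv), sum(cv$group == "CD"), sum(cv$group == "control"),
              paste(object@grid@dim, collapse = "x")))
  if (length(object@effectMasks))
    cat("  ground-truth effects:",
        paste(names(object@effectMasks), collapse = ", "), "\n")
})

setMethod("show", "AnalysisMask", function(object) {
  cat(sprintf("AnalysisMask: %d voxels (%.0f ul)\n",
              nVoxels(object), maskVolume(object)))
})

setMethod("show", "StatMaps", function(object) {
  cat(sprintf("StatMaps: terms [%s], df = %d, %d in-mask voxels\n",
              paste(names(object@beta), collapse = ", "),
              object@df, nVoxels(object@mask)))
  nc <- object@info$nNonConverged
  if (!is.null(nc) && nc > 0)
    cat(sprintf("  %d voxels did not converge\n", nc))
})

setMethod("show", "ClusterTable", function(object) {
  cat(sprintf("ClusterTable: %d surviving cluster(s)\n",
              nrow(object@table)))
  if (nrow(object@table)) print(object@table)
})

setMethod("show", "NullClusterDistribution", function(object) {
  cat(sprintf(
    "NullClusterDistribution: %d iterations, median max size %.0f voxels\n",
    length(object@maxSizes), median(object@maxSizes)))
})
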