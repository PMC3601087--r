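#' Voxel volume in microlitres
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @return Voxel volume in microlitres (1 mm^3 = 1 ul).
#' @export
voxelVolume <- function(grid) prod(voxelSize(grid))

#' Map 0-based voxel indices to world mm coordinates
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param ijk numeric matrix (n x 3) or length-3 vector of 0-based voxel
#'   indices.
#' @return n x 3 matrix of mm coordinates (RAS+ as encoded in the affine).
#' @export
voxelToWorld <- function(grid, ijk) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1)
  aff <- affineMatrix(grid)
  out <- cbind(ijk, 1) %*% t(aff)
  out[, 1:3, drop = FALSE]
}

# grids equal up to numerical noise
.sameGrid <- function(a, b, tol = 1e-6) {
  all(a@dim == b@dim) &&
    max(abs(a@voxelSize - b@voxelSize)) < tol &&
    max(abs(a@affine - b@affine)) < tol
}

# Extract the geometry of an RNifti image: voxel size from the affine
# column norms (the header pixdim is not trusted when an sform exists).
.gridFromNifti <- function(img) {
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  vs <- sqrt(colSums(aff[1:3, 1:3]^2))
  voxelGrid(dim(img), voxelSize = vs, affine = aff)
}

#' Write a volume as NIfTI-1
#'
#' Stat maps may contain NaN (outside the analysis mask) and negative
#' values; grey-matter maps are validated non-negative elsewhere.
#'
#' @param values 3D numeric array matching \code{grid}.
#' @param grid a \linkS4class{VoxelGrid}.
#' @param path output file (.nii or .nii.gz).
#' @param datatype NIfTI storage type, default lossless \code{"double"}.
#' @return \code{path}, invisibly.
#' @export
writeStatMap <- function(values, grid, path, datatype = "double") {
  if (!all(dim(values) == grid@dim))
    stop("values dimensions (", paste(dim(values), collapse = "x"),
         ") do not match grid (", paste(grid@dim, collapse = "x"), ")")
  img <- RNifti::asNifti(array(as.numeric(values), dim = grid@dim),
                         datatype = datatype)
  sf <- structure(affineMatrix(grid), code = 2L)
  img <- RNifti::`sform<-`(img, sf)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a statistic volume (values + geometry)
#'
#' @param path NIfTI file.
#' @return list with \code{values} (3D array) and \code{grid}.
#' @export
readStatMap <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, got shape ", paste(d, collapse = "x"),
         " in ", path)
  list(values = array(as.numeric(img), dim = d), grid = .gridFromNifti(img))
}

#' Read a subject grey-matter map
#'
#' Modulated GM maps are non-negative by construction; files containing
#' negative values (e.g. interpolation ringing) are rejected or clipped
#' at zero depending on \code{negatives}.
#'
#' @param path NIfTI file with a single 3D image.
#' @param subjectID subject identifier (defaults to the file stem).
#' @param negatives \code{"error"} (default) or \code{"clip"}.
#' @return A \linkS4class{GMMap}.
#' @export
readGMMap <- function(path, subjectID = NULL,
                      negatives = c("error", "clip")) {
  negatives <- match.arg(negatives)
  vol <- readStatMap(path)
  v <- vol$values
  if (any(v < 0)) {
    if (negatives == "error")
      stop("negative GM values in ", path,
           " (use negatives = 'clip' to zero them)")
    v[v < 0] <- 0
  }
  if (is.null(subjectID))
    subjectID <- sub("\\.nii(\\.gz)?$", "", basename(path))
  new("GMMap", values = v, grid = vol$grid, subjectID = subjectID)
}

#' Write a subject grey-matter map
#'
#' @param map a \linkS4class{GMMap}.
#' @param path output NIfTI file.
#' @return \code{path}, invisibly.
#' @export
writeGMMap <- function(map, path) {
  writeStatMap(map@values, map@grid, path)
}

#' Write an analysis mask as 8-bit NIfTI
#'
#' @param mask an \linkS4class{AnalysisMask}.
#' @param path output NIfTI file.
#' @return \code{path}, invisibly.
#' @export
writeAnalysisMask <- function(mask, path) {
  writeStatMap(array(as.numeric(mask@mask), dim = mask@grid@dim),
               mask@grid, path, datatype = "uint8")
}

#' Build the analysis mask from mean grey matter
#'
#' A voxel enters the mask when the mean GM value across all subjects
#' exceeds \code{meanThreshold}. The default 0.05 excludes background
#' while keeping all plausibly grey voxels; the mask rule is a package
#' choice, exposed as a parameter.
#'
#' @param x a \linkS4class{GMCohort}, a list of \linkS4class{GMMap}s, or
#'   a 4D array (then \code{grid} is required).
#' @param meanThreshold GM-units threshold on the across-subject mean.
#' @param grid required when \code{x} is a bare array.
#' @return An \linkS4class{AnalysisMask}.
#' @export
makeAnalysisMask <- function(x, meanThreshold = 0.05, grid = NULL) {
  if (is(x, "GMCohort")) {
    arr <- x@maps
    grid <- x@grid
  } else if (is.list(x)) {
    if (!length(x)) stop("need at least one map")
    grid <- x[[1]]@grid
    for (m in x)
      if (!.sameGrid(m@grid, grid)) stop("maps disagree on grid geometry")
    arr <- array(unlist(lapply(x, gmValues)), dim = c(grid@dim, length(x)))
  } else {
    if (is.null(grid)) stop("grid required for a bare array")
    arr <- x
  }
  mean3d <- apply(arr, c(1, 2, 3), mean)
  msk <- mean3d > meanThreshold
  if (!any(msk))
    stop("empty mask: no voxel has mean GM above ", meanThreshold)
  new("AnalysisMask", mask = msk, grid = grid)
}

# Centered ellipsoid support: semi-axes a fixed fraction of the grid
# half-extent. Connected, realistic-volume stand-in for brain support.
.ellipsoidMask <- function(dim, fraction = 0.8) {
  half <- (dim - 1) / 2
  ax <- pmax(half * fraction, 1)
  idx <- arrayInd(seq_len(prod(dim)), dim) - 1
  d2 <- ((idx[, 1] - half[1]) / ax[1])^2 +
        ((idx[, 2] - half[2]) / ax[2])^2 +
        ((idx[, 3] - half[3]) / ax[3])^2
  array(d2 <= 1, dim = dim)
}

#' Smooth a 3D volume with an isotropic Gaussian kernel
#'
#' Separable convolution with zero padding at the grid edges; the kernel
#' extends to 4 standard deviations per axis.
#'
#' @param values 3D numeric array.
#' @param sigmaMM kernel standard deviation in mm.
#' @param voxelSize voxel size triple in mm.
#' @return Smoothed array of the same shape.
#' @export
gaussianSmooth <- function(values, sigmaMM, voxelSize = c(2, 2, 2)) {
  voxelSize <- rep_len(voxelSize, 3L)
  if (sigmaMM < 0) stop("sigmaMM must be >= 0")
  if (sigmaMM == 0) return(values)
  .gaussianSmooth3dCpp(values, as.integer(dim(values)),
                       sigmaMM / voxelSize)
}
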