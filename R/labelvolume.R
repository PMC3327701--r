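# LabelVolume construction and NIfTI I/O.

#' Construct a LabelVolume
#'
#' @param grid 3-D array of non-negative integer labels (0 = background)
#' @param voxelDims numeric(3), voxel size in mm per axis
#' @param codes named character mapping label integers (names, as strings)
#'   to structure names
#' @return a \linkS4class{LabelVolume}
#' @export
LabelVolume <- function(grid, voxelDims = c(1, 1, 1), codes = character()) {
  storage.mode(grid) <- "integer"
  methods::new("LabelVolume", grid = grid, voxelDims = as.numeric(voxelDims),
               codes = codes)
}

#' @describeIn LabelVolume voxel volume in mm^3
#' @param x a LabelVolume
#' @export
voxelVolume <- function(x) prod(x@voxelDims)

#' @export
setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@grid)
  cat("LabelVolume:", paste(d, collapse = " x "), "voxels,",
      paste(signif(object@voxelDims, 4), collapse = " x "), "mm\n")
  labs <- setdiff(sort(unique(as.vector(object@grid))), 0L)
  cat(" ", length(labs), "labels,", length(object@codes), "named codes\n")
})

#' Read a label volume from NIfTI
#'
#' @param path NIfTI file (.nii or .nii.gz)
#' @param codes optional named character label dictionary
#' @return a \linkS4class{LabelVolume}
#' @export
readLabelVolume <- function(path, codes = character()) {
  img <- RNifti::readNifti(path)
  grid <- array(as.integer(round(img)), dim = dim(img))
  LabelVolume(grid, voxelDims = RNifti::pixdim(img)[1:3], codes = codes)
}

#' Write a label volume to NIfTI
#'
#' @param x a LabelVolume
#' @param path output NIfTI path
#' @export
writeLabelVolume <- function(x, path) {
  stopifnot(methods::is(x, "LabelVolume"))
  g <- x@grid
  attr(g, "pixdim") <- x@voxelDims
  RNifti::writeNifti(RNifti::asNifti(g, datatype = "int16"), path)
  invisible(path)
}
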