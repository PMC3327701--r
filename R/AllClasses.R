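#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' TleCohort: a cohort of subjects with regional brain volumes
#'
#' Extends \linkS4class{SummarizedExperiment}: rows are the 83 catalog
#' structures, columns are subjects. The single assay \code{"volumes"} holds
#' regional volumes in mm^3 (raw) or dimensionless volume/ICV ratios
#' (normalized; see \code{\link{isNormalized}}). Column data carries
#' \code{group}, \code{side}, \code{age}, \code{sex} and \code{icv_cm3};
#' any further columns are opaque metadata and never enter the analysis.
#'
#' @slot .   inherits all slots from SummarizedExperiment
#' @export
setClass("TleCohort", contains = "SummarizedExperiment")

setValidity("TleCohort", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("group", "side", "age", "sex", "icv_cm3")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("missing colData columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate subject ids")
  if (!"volumes" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'volumes' is required")
  if ("icv_cm3" %in% colnames(cd) && any(cd$icv_cm3 <= 0))
    msg <- c(msg, "all icv_cm3 must be > 0")
  v <- SummarizedExperiment::assay(object, "volumes")
  if (any(v < 0)) msg <- c(msg, "volumes must be >= 0")
  if (length(msg)) msg else TRUE
})

#' LabelVolume: a 3-D integer label image
#'
#' A voxel grid of non-negative integer region labels (0 = background),
#' with voxel dimensions in mm and a code-to-structure-name dictionary.
#'
#' @slot grid 3-D integer array of labels
#' @slot voxelDims numeric(3), mm per axis
#' @slot codes named character: names are label integers (as strings),
#'   values are structure names
#' @export
setClass("LabelVolume", representation(
  grid = "array", voxelDims = "numeric", codes = "character"))

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@grid)) != 3L) msg <- c(msg, "grid must be 3-D")
  if (length(object@voxelDims) != 3L || any(object@voxelDims <= 0))
    msg <- c(msg, "voxelDims must be 3 positive values")
  g <- object@grid
  if (any(g < 0) || any(g != round(g)))
    msg <- c(msg, "labels must be non-negative integers")
  if (length(object@codes) && is.null(names(object@codes)))
    msg <- c(msg, "codes must be named by label integer")
  if (length(msg)) msg else TRUE
})

#' StructureRanking: structures ordered by class-separability criterion
#'
#' @slot entries DataFrame with columns \code{structure} and \code{J}
#'   (criterion value, >= 0), sorted non-increasing in \code{J}; ties keep
#'   canonical catalog order
#' @slot D number of selected (top-ranked) structures
#' @slot params list echoing the separability parameters used
#' @export
setClass("StructureRanking", representation(
  entries = "DataFrame", D = "integer", params = "list"))

setValidity("StructureRanking", function(object) {
  msg <- character()
  e <- object@entries
  if (!all(c("structure", "J") %in% colnames(e)))
    msg <- c(msg, "entries needs columns 'structure' and 'J'")
  else {
    if (is.unsorted(rev(e$J))) msg <- c(msg, "entries must be sorted by J, descending")
    if (any(e$J < 0)) msg <- c(msg, "criterion values must be >= 0")
  }
  if (object@D < 0L || object@D > nrow(e))
    msg <- c(msg, "D must be in [0, nrow(entries)]")
  if (length(msg)) msg else TRUE
})

#' SpectralFeatures: per-subject features from per-structure graph Laplacians
#'
#' For each selected structure, subjects are embedded with the k smallest
#' eigenvectors of the Laplacian of the Gaussian similarity graph on z-scored
#' volumes; the blocks are concatenated structure-major into an N x kD matrix.
#'
#' @slot matrix N x kD numeric matrix, rows = subjects in cohort order,
#'   columns named \code{<structure>.ev<j>}
#' @slot structures ordered character vector of the D structures
#' @slot k eigenvectors per structure
#' @slot c Gaussian similarity constant
#' @slot laplacianVariant "unnormalized" or "symmetric"
#' @export
setClass("SpectralFeatures", representation(
  matrix = "matrix", structures = "character", k = "integer",
  c = "numeric", laplacianVariant = "character"))

setValidity("SpectralFeatures", function(object) {
  msg <- character()
  if (ncol(object@matrix) != object@k * length(object@structures))
    msg <- c(msg, "column count must equal k * D")
  if (object@c <= 0) msg <- c(msg, "similarity constant c must be > 0")
  if (!object@laplacianVariant %in% c("unnormalized", "symmetric"))
    msg <- c(msg, "laplacianVariant must be 'unnormalized' or 'symmetric'")
  if (length(msg)) msg else TRUE
})
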