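# Regional volumetry: grey-matter-masked volumes from label images and
# ICV normalization of cohort tables.

#' Regional volumes from a label image and a grey-matter probability map
#'
#' For structures under grey-matter masking, only voxels with the structure's
#' label \emph{and} GM probability strictly above 0.5 are counted; the
#' gm-exempt structures (ventricles, corpus callosum, and subcortical grey
#' nuclei whose GM probability is typically misclassified at or below 50%)
#' are counted as full structures. Volumes are voxel counts times voxel
#' volume, in mm^3.
#'
#' @param labels a \linkS4class{LabelVolume} whose codes name catalog
#'   structures
#' @param gm_probability 3-D numeric array in [0, 1], same grid as
#'   \code{labels}
#' @param catalog structure catalog data.frame (default
#'   \code{\link{structureCatalog}()})
#' @return named numeric over all catalog structures (mm^3); structures with
#'   no labelled voxels get 0. Label codes not naming a catalog structure
#'   raise a warning and are ignored.
#' @export
regionalVolumes <- function(labels, gm_probability,
                            catalog = structureCatalog()) {
  stopifnot(methods::is(labels, "LabelVolume"))
  if (!identical(dim(labels@grid), dim(gm_probability)))
    stop("labels and gm_probability grids differ")
  if (any(gm_probability < 0 | gm_probability > 1))
    stop("gm_probability must lie in [0, 1]")
  unknown <- setdiff(unname(labels@codes), catalog$name)
  if (length(unknown))
    warning("label codes not in catalog, ignored: ",
            paste(unknown, collapse = ", "))
  vv <- voxelVolume(labels)
  gm_mask <- gm_probability > 0.5  # strict: ties at exactly 0.5 excluded
  vols <- stats::setNames(numeric(nrow(catalog)), catalog$name)
  for (i in seq_along(labels@codes)) {
    nm <- unname(labels@codes[i])
    if (!nm %in% catalog$name) next
    code <- as.integer(names(labels@codes)[i])
    in_region <- labels@grid == code
    exempt <- catalog$gm_exempt[match(nm, catalog$name)]
    n <- if (exempt) sum(in_region) else sum(in_region & gm_mask)
    vols[nm] <- vols[nm] + n * vv
  }
  vols
}

#' Normalize cohort volumes by intracranial volume
#'
#' Replaces each volume (mm^3) by the dimensionless ratio volume / ICV
#' (ICV converted from cm^3 to mm^3) and sets the normalized flag.
#' Normalizing twice is an error; within-subject volume ratios are
#' preserved exactly.
#'
#' @param cohort an unnormalized \linkS4class{TleCohort}
#' @return the normalized \linkS4class{TleCohort}
#' @export
normalizeByIcv <- function(cohort) {
  stopifnot(methods::is(cohort, "TleCohort"))
  if (isNormalized(cohort)) stop("cohort is already ICV-normalized")
  icv <- subjectData(cohort)$icv_cm3
  bad <- which(icv <= 0)
  if (length(bad))
    stop("non-positive ICV for subject(s): ",
         paste(colnames(cohort)[bad], collapse = ", "))
  v <- sweep(volumes(cohort), 2, icv * 1000, "/")
  out <- cohort
  SummarizedExperiment::assay(out, "volumes") <- v
  S4Vectors::metadata(out)$normalized <- TRUE
  out
}
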