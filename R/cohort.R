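# TleCohort construction, accessors and delimited-text I/O.

#' Construct a TleCohort
#'
#' @param volumes numeric matrix, 83 structures (rows, canonical order) x
#'   subjects (columns); mm^3 unless \code{normalized}
#' @param subjectData data.frame or DataFrame with one row per subject and
#'   at least \code{group}, \code{side}, \code{age}, \code{sex},
#'   \code{icv_cm3}; extra columns are carried as opaque metadata
#' @param normalized logical; \code{TRUE} if volumes are already ICV ratios
#' @return a \linkS4class{TleCohort}
#' @export
TleCohort <- function(volumes, subjectData, normalized = FALSE) {
  if (is.null(rownames(volumes)))
    stop("volumes must have structure row names")
  miss <- setdiff(structureNames(), rownames(volumes))
  if (length(miss))
    stop("missing structure rows: ", paste(miss, collapse = ", "))
  volumes <- volumes[structureNames(), , drop = FALSE]
  cd <- S4Vectors::DataFrame(subjectData)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(volumes = volumes), colData = cd)
  obj <- methods::new("TleCohort", se)
  S4Vectors::metadata(obj)$normalized <- isTRUE(normalized)
  methods::validObject(obj)
  obj
}

#' Volume matrix of a cohort
#' @param x a TleCohort
#' @return numeric matrix, structures x subjects
#' @export
volumes <- function(x) {
  stopifnot(methods::is(x, "TleCohort"))
  SummarizedExperiment::assay(x, "volumes")
}

#' Subject metadata of a cohort
#' @param x a TleCohort
#' @return DataFrame, one row per subject
#' @export
subjectData <- function(x) {
  stopifnot(methods::is(x, "TleCohort"))
  SummarizedExperiment::colData(x)
}

#' Is the cohort ICV-normalized?
#' @param x a TleCohort
#' @return logical
#' @export
isNormalized <- function(x) isTRUE(S4Vectors::metadata(x)$normalized)

#' @export
setMethod("show", "TleCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("TleCohort:", ncol(object), "subjects x", nrow(object), "structures\n")
  cat("  normalized:", isNormalized(object), "\n")
  if (ncol(object)) {
    tab <- table(cd$group)
    cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

.cohort_meta_cols <- c("subject_id", "group", "side", "age", "sex", "icv_cm3")

#' Write a cohort as delimited text
#'
#' Header is \code{subject_id, group, side, age, sex, icv_cm3}, then the 83
#' structure columns in canonical order, then any extra metadata columns.
#' Numeric values keep full precision (15 significant digits), so a
#' write/read round trip is lossless well beyond 6 significant digits.
#'
#' @param cohort a TleCohort
#' @param path output file path
#' @param sep field separator (default comma)
#' @export
writeCohort <- function(cohort, path, sep = ",") {
  stopifnot(methods::is(cohort, "TleCohort"))
  cd <- as.data.frame(subjectData(cohort))
  extra <- setdiff(colnames(cd), .cohort_meta_cols)
  df <- data.frame(subject_id = colnames(cohort),
                   cd[, c("group", "side", "age", "sex", "icv_cm3"), drop = FALSE],
                   t(volumes(cohort)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (length(extra)) df <- cbind(df, cd[, extra, drop = FALSE])
  attr(df, "normalized") <- isNormalized(cohort)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  # normalized flag in a header comment is fragile across parsers; encode it
  # as a column only when TRUE
  if (isNormalized(cohort)) {
    lines <- readLines(path)
    writeLines(c("# normalized: TRUE", lines), path)
  }
  invisible(path)
}

#' Read a cohort from delimited text
#'
#' @param path file written by \code{\link{writeCohort}} (or matching its
#'   schema); unknown extra columns are preserved as subject metadata and
#'   never treated as structures
#' @param sep field separator
#' @return a TleCohort
#' @export
readCohort <- function(path, sep = ",") {
  first <- readLines(path, n = 1L)
  normalized <- grepl("^#\\s*normalized:\\s*TRUE", first)
  df <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c(.cohort_meta_cols, structureNames())
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("cohort file is missing required columns: ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in cohort file: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  vol <- t(as.matrix(df[, structureNames(), drop = FALSE]))
  colnames(vol) <- df$subject_id
  extra <- setdiff(colnames(df), need)
  cd <- df[, c("group", "side", "age", "sex", "icv_cm3", extra), drop = FALSE]
  rownames(cd) <- df$subject_id
  TleCohort(vol, cd, normalized = normalized)
}
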