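# Vote-rule decision fusion of candidate segmentations and region-wise
# overlap evaluation.

.check_same_grid <- function(vols) {
  dims <- lapply(vols, function(v) dim(v@grid))
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("label volumes have mismatching grids")
  vd <- lapply(vols, function(v) v@voxelDims)
  if (!all(vapply(vd, function(d) isTRUE(all.equal(d, vd[[1]])), TRUE)))
    stop("label volumes have mismatching voxel dimensions")
  invisible(TRUE)
}

#' Vote-rule decision fusion of label volumes
#'
#' Per voxel, the output label is the modal label across candidates; ties
#' are broken deterministically toward the lowest label code (so fusion is
#' independent of candidate order).
#'
#' @param candidates non-empty list of \linkS4class{LabelVolume}s on
#'   identical grids
#' @return the fused \linkS4class{LabelVolume}; codes are merged from the
#'   candidates
#' @export
voteFuse <- function(candidates) {
  if (!length(candidates)) stop("empty candidate list")
  stopifnot(all(vapply(candidates, methods::is, TRUE, "LabelVolume")))
  .check_same_grid(candidates)
  labs <- sort(unique(unlist(lapply(candidates, function(v)
    unique(as.vector(v@grid))))))
  nvox <- length(candidates[[1]]@grid)
  best_count <- rep(-1L, nvox)
  best_lab <- integer(nvox)
  for (lab in labs) {  # ascending: strict > keeps the lowest code on ties
    cnt <- integer(nvox)
    for (v in candidates) cnt <- cnt + (as.vector(v@grid) == lab)
    win <- cnt > best_count
    best_lab[win] <- lab
    best_count[win] <- cnt[win]
  }
  codes <- do.call(c, lapply(candidates, function(v) v@codes))
  codes <- codes[!duplicated(names(codes))]
  LabelVolume(array(best_lab, dim = dim(candidates[[1]]@grid)),
              voxelDims = candidates[[1]]@voxelDims, codes = codes)
}

.region_code <- function(x, region) {
  hit <- names(x@codes)[x@codes == region]
  if (length(hit)) as.integer(hit[1]) else NA_integer_
}

#' Dice overlap of a region between two label volumes
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; returns 1 when both region sets are
#' empty. Symmetric and invariant to voxel dimensions. The Jaccard index
#' \eqn{|A \cap B| / |A \cup B|} is available via \code{metric}.
#'
#' @param a,b \linkS4class{LabelVolume}s on the same grid
#' @param region structure name, present in the codes of at least one input
#' @param metric "dice" (default) or "jaccard"
#' @return overlap fraction in [0, 1]
#' @export
diceOverlap <- function(a, b, region, metric = c("dice", "jaccard")) {
  metric <- match.arg(metric)
  .check_same_grid(list(a, b))
  ca <- .region_code(a, region); cb <- .region_code(b, region)
  if (is.na(ca) && is.na(cb))
    stop("region '", region, "' not present in either volume's codes")
  if (is.na(ca)) ca <- cb
  if (is.na(cb)) cb <- ca
  inA <- as.vector(a@grid) == ca
  inB <- as.vector(b@grid) == cb
  nA <- sum(inA); nB <- sum(inB); nAB <- sum(inA & inB)
  if (nA + nB == 0L) return(1)
  if (metric == "dice") 2 * nAB / (nA + nB) else nAB / (nA + nB - nAB)
}

#' Compare two segmentation sets against a reference, region by region
#'
#' For each region, computes the difference of mean overlaps,
#' mean(overlap(set_a, reference)) - mean(overlap(set_b, reference)), plus
#' a summary mean +/- SD over regions.
#'
#' @param set_a,set_b lists of \linkS4class{LabelVolume}s indexing the same
#'   targets (equal lengths)
#' @param reference a \linkS4class{LabelVolume} whose codes define the
#'   evaluated regions
#' @param metric overlap metric, "dice" (default) or "jaccard"
#' @return list with \code{per_region} (data.frame: region, mean_a, mean_b,
#'   difference) and \code{summary} (mean, sd over regions)
#' @export
overlapComparison <- function(set_a, set_b, reference,
                              metric = c("dice", "jaccard")) {
  metric <- match.arg(metric)
  if (length(set_a) != length(set_b))
    stop("set_a and set_b must have equal length")
  if (!length(reference@codes)) stop("reference has no region codes")
  regions <- unname(reference@codes)
  per <- lapply(regions, function(rg) {
    da <- vapply(set_a, diceOverlap, 0, b = reference, region = rg,
                 metric = metric)
    db <- vapply(set_b, diceOverlap, 0, b = reference, region = rg,
                 metric = metric)
    c(mean_a = mean(da), mean_b = mean(db), difference = mean(da) - mean(db))
  })
  df <- data.frame(region = regions, do.call(rbind, per),
                   stringsAsFactors = FALSE)
  sdv <- if (nrow(df) > 1) stats::sd(df$difference) else 0
  list(per_region = df,
       summary = c(mean = mean(df$difference), sd = sdv))
}
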