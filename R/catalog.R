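# Canonical 83-structure catalog, shipped as a versioned JSON resource.

.pkg_env <- new.env(parent = emptyenv())

#' The canonical 83-structure catalog
#'
#' Returns the package's canonical whole-brain structure catalog: 83 named
#' regions (40 bilateral pairs plus brainstem, corpus callosum and third
#' ventricle), of which 18 are "full structures" exempt from grey-matter
#' masking (ventricular spaces, corpus callosum, and the subcortical grey
#' nuclei whose GM probability is typically misclassified at or below 50%:
#' caudate, accumbens, pallidum, putamen, substantia nigra, thalamus,
#' brainstem).
#'
#' @return a data.frame with columns \code{name}, \code{full_name},
#'   \code{hemisphere} (L/R/M), \code{lobe}, \code{gm_exempt},
#'   \code{typical_volume_mm3} and \code{index}, in canonical order.
#' @examples
#' cat83 <- structureCatalog()
#' nrow(cat83)            # 83
#' sum(cat83$gm_exempt)   # 18
#' @export
structureCatalog <- function() {
  if (is.null(.pkg_env$catalog)) {
    path <- system.file("extdata", "structure_catalog.json",
                        package = "tleMorph", mustWork = TRUE)
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    cat83 <- as.data.frame(raw$structures, stringsAsFactors = FALSE)
    stopifnot(nrow(cat83) == 83L, sum(cat83$gm_exempt) == 18L)
    .pkg_env$catalog <- cat83[order(cat83$index), ]
  }
  .pkg_env$catalog
}

#' Canonical structure names
#' @return character(83) in canonical catalog order
#' @export
structureNames <- function() structureCatalog()$name

#' Grey-matter-exempt structure names
#' @return character(18), the full-structure (unmasked) subset
#' @export
gmExemptStructures <- function() {
  cat83 <- structureCatalog()
  cat83$name[cat83$gm_exempt]
}

#' Swap hemisphere suffixes of structure names
#'
#' Maps \code{_L} names to their \code{_R} homologue and vice versa; midline
#' structures map to themselves. Used to reflect ipsilaterally-defined
#' atrophy effects onto the opposite hemisphere for left/right focus groups.
#'
#' @param names character vector of catalog structure names
#' @return character vector of the contralateral homologues
#' @examples
#' sideSwap(c("Hippocampus_L", "Brainstem"))
#' @export
sideSwap <- function(names) {
  stopifnot(all(names %in% structureNames()))
  out <- names
  left <- grepl("_L$", names)
  right <- grepl("_R$", names)
  out[left] <- sub("_L$", "_R", names[left])
  out[right] <- sub("_R$", "_L", names[right])
  stopifnot(all(out %in% structureNames()))
  out
}
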