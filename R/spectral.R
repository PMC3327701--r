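# Spectral features: per-structure Gaussian similarity graphs, graph
# Laplacians, and eigenvector embeddings concatenated into an N x kD
# feature matrix.

#' Z-score a vector of per-subject volumes
#'
#' Population convention (divisor N): mean 0 and SD-with-divisor-N of 1.
#'
#' @param values numeric, >= 2 subjects
#' @param structure optional structure name for error messages
#' @return z-scores
#' @examples
#' zscoreVolumes(c(2, 4, 6))  # -1.2247, 0, 1.2247
#' @export
zscoreVolumes <- function(values, structure = NULL) {
  if (length(values) < 2) stop("need >= 2 subjects")
  s <- sqrt(mean((values - mean(values))^2))
  if (!is.finite(s) || s == 0)
    stop("zero standard deviation",
         if (!is.null(structure)) paste0(" for structure '", structure, "'"))
  (values - mean(values)) / s
}

#' Gaussian similarity matrix of z-scored volumes
#'
#' \eqn{W_{ij} = \exp(-(z_i - z_j)^2 / c)}: a complete, undirected subject
#' graph weighted by volumetric similarity (heat kernel). Symmetric, unit
#' diagonal, all entries in (0, 1]; depends on z only through differences.
#'
#' @param z numeric z-scores
#' @param c similarity constant (default 2)
#' @return N x N similarity matrix
#' @export
similarityMatrix <- function(z, c = 2) {
  if (!all(is.finite(z))) stop("z must be finite")
  if (c <= 0) stop("c must be > 0")
  exp(-outer(z, z, "-")^2 / c)
}

#' Graph Laplacian of a similarity matrix
#'
#' Unnormalized: \eqn{L = Deg - W}; symmetric normalized:
#' \eqn{L = I - Deg^{-1/2} W Deg^{-1/2}}. Both are symmetric positive
#' semidefinite with smallest eigenvalue 0 on a connected graph.
#'
#' @param W symmetric non-negative similarity matrix
#' @param variant "unnormalized" (default) or "symmetric"
#' @return the Laplacian matrix
#' @export
graphLaplacian <- function(W, variant = c("unnormalized", "symmetric")) {
  variant <- match.arg(variant)
  if (!isSymmetric(unname(W), tol = 1e-10)) stop("W must be symmetric")
  if (any(W < 0)) stop("W must be non-negative")
  deg <- rowSums(W)
  if (variant == "unnormalized") {
    diag(deg) - W
  } else {
    if (any(deg <= 0)) stop("symmetric variant needs positive degrees")
    dhalf <- 1 / sqrt(deg)
    diag(nrow(W)) - (dhalf %o% dhalf) * W
  }
}

#' Spectral embedding: eigenvectors of the k smallest Laplacian eigenvalues
#'
#' Columns are unit-norm eigenvectors in ascending eigenvalue order, each
#' sign-fixed so its largest-magnitude entry (first such entry on magnitude
#' ties) is positive — a deterministic convention so repeated runs yield
#' byte-identical features.
#'
#' @param L symmetric PSD Laplacian
#' @param k number of eigenvectors, k < N
#' @return N x k matrix of eigenvector columns
#' @export
spectralEmbed <- function(L, k) {
  n <- nrow(L)
  if (k >= n) stop("k must be < number of subjects (", n, ")")
  es <- eigen(L, symmetric = TRUE)  # eigenvalues descending
  idx <- seq(n, n - k + 1)          # k smallest, ascending
  V <- es$vectors[, idx, drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Build the N x kD spectral feature matrix
#'
#' For each selected structure: z-score the (normalized) volumes over all N
#' subjects, form the Gaussian similarity graph, take its Laplacian, and
#' embed with the k smallest eigenvectors. Blocks are concatenated
#' structure-major, eigenvector-minor. The embedding is transductive (all
#' subjects in the experiment enter the graph); see the vignette for the
#' leakage caveat and the train-only alternative used in evaluation.
#'
#' @param cohort a normalized \linkS4class{TleCohort}
#' @param selected a \linkS4class{StructureRanking}, or a character vector
#'   of structure names
#' @param k eigenvectors per structure (default 2)
#' @param c Gaussian similarity constant (default 2)
#' @param variant Laplacian variant
#' @param skip_trivial drop the first (trivial, near-constant) eigenvector
#'   and use eigenvectors 2..k+1 instead (default FALSE)
#' @return a \linkS4class{SpectralFeatures}
#' @export
buildFeatureMatrix <- function(cohort, selected, k = 2L, c = 2,
                               variant = c("unnormalized", "symmetric"),
                               skip_trivial = FALSE) {
  variant <- match.arg(variant)
  stopifnot(methods::is(cohort, "TleCohort"))
  if (!isNormalized(cohort)) stop("cohort must be ICV-normalized")
  structures <- if (methods::is(selected, "StructureRanking"))
    selectedStructures(selected) else as.character(selected)
  if (!length(structures)) stop("no structures selected")
  X <- t(volumes(cohort))  # subjects x structures
  k <- as.integer(k)
  blocks <- lapply(structures, function(s) {
    z <- zscoreVolumes(X[, s], structure = s)
    L <- graphLaplacian(similarityMatrix(z, c = c), variant = variant)
    kk <- if (skip_trivial) k + 1L else k
    V <- spectralEmbed(L, kk)
    if (skip_trivial) V <- V[, -1L, drop = FALSE]
    colnames(V) <- paste0(s, ".ev", seq_len(k))
    V
  })
  M <- do.call(cbind, blocks)
  rownames(M) <- colnames(cohort)
  methods::new("SpectralFeatures", matrix = M, structures = structures,
               k = k, c = c, laplacianVariant = variant)
}

#' Feature matrix of a SpectralFeatures object
#' @param x a SpectralFeatures
#' @return the N x kD numeric matrix
#' @export
featureMatrix <- function(x) {
  stopifnot(methods::is(x, "SpectralFeatures"))
  x@matrix
}

#' @export
setMethod("show", "SpectralFeatures", function(object) {
  cat("SpectralFeatures:", nrow(object@matrix), "subjects x",
      ncol(object@matrix), "features (k =", object@k, ", D =",
      length(object@structures), ", c =", object@c, ",",
      object@laplacianVariant, "Laplacian)\n")
})

# Nystrom-style out-of-sample extension for the unnormalized Laplacian:
# from the eigenpair equation at a new point, u_new = (w . u) / (d - lambda)
# with w the similarity vector to the training points and d = sum(w).
.nystrom_extend <- function(z_train, z_new, V, lambda, c = 2) {
  out <- vapply(seq_along(z_new), function(i) {
    w <- exp(-(z_train - z_new[i])^2 / c)
    d <- sum(w)
    denom <- d - lambda
    denom[abs(denom) < 1e-8] <- sign(denom[abs(denom) < 1e-8] + 1e-12) * 1e-8
    as.numeric(crossprod(V, w)) / denom
  }, numeric(ncol(V)))
  t(matrix(out, nrow = ncol(V)))
}
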