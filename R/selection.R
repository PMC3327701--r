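# Kernel-based two-class separability criterion and Best Individual N
# structure ranking.

#' Separability criterion parameters
#'
#' @param kernel "gaussian" (default) or "linear"
#' @param sigma Gaussian kernel bandwidth on z-scored values; \code{NULL}
#'   (default) uses the median heuristic: the median of pairwise absolute
#'   differences, floored at 1e-3
#' @param epsilon denominator guard added to the within-class scatter
#' @return classed list of parameters
#' @export
separabilityParams <- function(kernel = c("gaussian", "linear"), sigma = NULL,
                               epsilon = 1e-8) {
  kernel <- match.arg(kernel)
  if (!is.null(sigma) && sigma <= 0) stop("sigma must be > 0")
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1)")
  structure(list(kernel = kernel, sigma = sigma, epsilon = epsilon),
            class = "SeparabilityParams")
}

.kernel_matrix <- function(x, params) {
  if (params$kernel == "linear") return(outer(x, x))
  sigma <- params$sigma
  if (is.null(sigma)) {
    d <- abs(outer(x, x, "-"))
    sigma <- max(stats::median(d[upper.tri(d)]), 1e-3)
  }
  exp(-outer(x, x, "-")^2 / (2 * sigma^2))
}

# J from a precomputed kernel matrix and a two-level label factor.
# between = ||mu_1 - mu_2||^2 in the RKHS (A + B - 2C with full double-sum
# means including the diagonal); within = sum over classes of the mean
# squared RKHS distance to the class mean, E[k(x,x)] - E[k(x,x')].
.J_from_kernel <- function(K, labels, epsilon) {
  lev <- levels(labels)
  i1 <- which(labels == lev[1]); i2 <- which(labels == lev[2])
  A <- mean(K[i1, i1]); B <- mean(K[i2, i2]); C <- mean(K[i1, i2])
  between <- A + B - 2 * C
  within <- (mean(diag(K)[i1]) - A) + (mean(diag(K)[i2]) - B)
  if (between <= 0) return(max(between, 0) / (within + epsilon))
  between / (within + epsilon)
}

#' Kernel-based two-class separability criterion
#'
#' Ratio of the squared distance between the two class means in the
#' kernel-induced feature space to the summed within-class scatter:
#' \deqn{J = \frac{\|\mu_1 - \mu_2\|^2_H}{s_1 + s_2 + \epsilon}} with
#' \eqn{s_c = E[k(x,x)] - E_{x,x' \in c}[k(x,x')]}. Makes no assumption on
#' the class-conditional densities; with the linear kernel it reduces
#' exactly to the Fisher-style ratio (difference of class means squared
#' over summed within-class population variances).
#'
#' @param values numeric per-subject scalar feature
#' @param labels two-class factor (or coercible), both classes >= 2 members
#' @param params a \code{\link{separabilityParams}}
#' @return criterion value J >= 0
#' @examples
#' kernelSeparability(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3),
#'                    separabilityParams("linear"))
#' @export
kernelSeparability <- function(values, labels,
                               params = separabilityParams()) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2)
    stop("exactly two classes required, got ", nlevels(labels))
  if (any(table(labels) < 2))
    stop("each class needs >= 2 members")
  if (length(values) != length(labels)) stop("length mismatch")
  if (!all(is.finite(values))) stop("values must be finite")
  .J_from_kernel(.kernel_matrix(values, params), labels, params$epsilon)
}

#' Rank structures by separability (Best Individual N)
#'
#' Applies the kernel separability criterion independently to each of the
#' 83 structure columns (z-scored first, so J is comparable across
#' structures of different absolute volume) and ranks them by J, descending.
#' Ties keep canonical catalog order. Zero-variance structures get J = 0.
#'
#' @param cohort a normalized \linkS4class{TleCohort}
#' @param labels two-class labels over the cohort's subjects (cohort order)
#' @param params a \code{\link{separabilityParams}}
#' @param D number of top structures to flag as selected
#' @return a \linkS4class{StructureRanking}
#' @export
rankStructuresBin <- function(cohort, labels, params = separabilityParams(),
                              D = 10L) {
  stopifnot(methods::is(cohort, "TleCohort"))
  if (!isNormalized(cohort))
    stop("cohort must be ICV-normalized before ranking")
  X <- volumes(cohort)
  .rank_matrix_bin(t(X), labels, params, D)
}

# Internal BIN over a subjects x structures matrix (column order defines the
# tie-break ordering).
.rank_matrix_bin <- function(X, labels, params, D) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2) stop("exactly two classes required")
  D <- as.integer(D)
  if (D > ncol(X)) stop("D (", D, ") exceeds the number of structures (",
                        ncol(X), ")")
  J <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(0)  # constant feature: between = 0
    z <- (x - mean(x)) / s
    .J_from_kernel(.kernel_matrix(z, params), labels, params$epsilon)
  }, 0)
  ord <- order(-J, seq_along(J))  # ties: canonical column order
  entries <- S4Vectors::DataFrame(structure = colnames(X)[ord], J = J[ord])
  methods::new("StructureRanking", entries = entries, D = D,
               params = unclass(params))
}

#' Selected (top-D) structures of a ranking
#' @param x a StructureRanking
#' @return character(D) in rank order
#' @export
selectedStructures <- function(x) {
  stopifnot(methods::is(x, "StructureRanking"))
  utils::head(x@entries$structure, x@D)
}

#' Criterion values of a ranking
#' @param x a StructureRanking
#' @return named numeric, J per structure in rank order
#' @export
criterionValues <- function(x) {
  stopifnot(methods::is(x, "StructureRanking"))
  stats::setNames(x@entries$J, x@entries$structure)
}

#' @export
setMethod("show", "StructureRanking", function(object) {
  cat("StructureRanking:", nrow(object@entries), "structures, top D =",
      object@D, "\n")
  top <- utils::head(object@entries, min(5L, nrow(object@entries)))
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %2d. %-20s J = %.4g\n", i, top$structure[i], top$J[i]))
})
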