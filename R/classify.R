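# Two SVM classification schemes (RBF on volumes, linear on spectral
# features), nested grid search, repeated stratified cross-validation,
# side-specific classifier combination, and permutation testing.

#' Specify a classifier
#'
#' @param scheme "volumetric" (RBF-SVM on selected ICV-normalized volumes)
#'   or "spectral" (linear SVM on spectral features of selected structures)
#' @param C_grid slack-penalty candidates (default \eqn{2^{-5}, 2^{-3},
#'   \ldots, 2^{15}})
#' @param gamma_grid RBF width candidates (default \eqn{2^{-15}, 2^{-13},
#'   \ldots, 2^{3}}); ignored for the linear kernel
#' @param D_grid candidate numbers of selected structures (default 1..20)
#' @param k eigenvectors per structure (spectral scheme)
#' @param c Gaussian similarity constant (spectral scheme)
#' @param embed "transductive" (graph over all subjects in the experiment;
#'   default, with a known leakage caveat documented in the vignette) or
#'   "nystrom" (train-only graph, out-of-sample extension for test subjects)
#' @param laplacian Laplacian variant for the spectral scheme
#' @param sep_params \code{\link{separabilityParams}} used for ranking
#' @param inner_cv inner model-selection scheme; "loo" (leave-one-out)
#' @return a classed list; kernel is "rbf" for volumetric, "linear" for
#'   spectral
#' @export
classifierSpec <- function(scheme = c("volumetric", "spectral"),
                           C_grid = 2^seq(-5, 15, by = 2),
                           gamma_grid = 2^seq(-15, 3, by = 2),
                           D_grid = 1:20, k = 2L, c = 2,
                           embed = c("transductive", "nystrom"),
                           laplacian = c("unnormalized", "symmetric"),
                           sep_params = separabilityParams(),
                           inner_cv = "loo") {
  scheme <- match.arg(scheme)
  embed <- match.arg(embed)
  laplacian <- match.arg(laplacian)
  if (!length(C_grid) || any(C_grid <= 0)) stop("C_grid must be positive")
  if (!length(gamma_grid) || any(gamma_grid <= 0))
    stop("gamma_grid must be positive")
  if (!length(D_grid) || any(D_grid < 1)) stop("D_grid must be >= 1")
  structure(list(
    scheme = scheme,
    kernel = if (scheme == "volumetric") "rbf" else "linear",
    C_grid = sort(C_grid), gamma_grid = sort(gamma_grid),
    D_grid = sort(as.integer(D_grid)), k = as.integer(k), c = c,
    embed = embed, laplacian = laplacian, sep_params = sep_params,
    inner_cv = inner_cv), class = "ClassifierSpec")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), accuracy =
#' (tp+tn)/total, all in percent. A metric with an empty denominator is
#' returned as NA with a warning, never silently 0.
#'
#' @param tp,fn,tn,fp non-negative confusion counts (positives = patients)
#' @return named numeric: accuracy, sensitivity, specificity (%)
#' @export
metricsFromConfusion <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  total <- tp + fn + tn + fp
  if (total == 0) stop("no observations")
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else {
    warning("sensitivity undefined: no positive cases"); NA_real_ }
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else {
    warning("specificity undefined: no negative cases"); NA_real_ }
  c(accuracy = 100 * (tp + tn) / total, sensitivity = sens,
    specificity = spec)
}

# Choose the positive class (patients; left-focus for lateralization).
.default_positive <- function(lev) {
  if ("control" %in% lev) return(setdiff(lev, "control")[1])
  l <- grep("_L$", lev, value = TRUE)
  if (length(l) == 1) return(l)
  lev[1]
}

# Train-set column standardization (zero-variance columns pass through).
.scale_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}
.scale_apply <- function(X, sc)
  sweep(sweep(X, 2, sc$center, "-"), 2, sc$scale, "/")

.svm_kernel <- function(spec) if (spec$kernel == "rbf") "radial" else "linear"

# LOO accuracy of one grid point via libsvm's internal cross-validation
# (deterministic for LOO: every fold is a singleton).
.loo_accuracy <- function(features, y, spec, C, gamma) {
  fit <- e1071::svm(features, y, kernel = .svm_kernel(spec), cost = C,
                    gamma = gamma, scale = FALSE, cross = length(y))
  fit$tot.accuracy
}

# Structure-major column block of a spectral feature matrix.
.spectral_cols <- function(sf, structs) {
  idx <- unlist(lapply(structs, function(s)
    which(sf@structures == s)[1] * sf@k - (sf@k - 1):0))
  sf@matrix[, idx, drop = FALSE]
}

# Feature matrix for a given set of selected structures.
#  volumetric: the selected columns of the subjects x structures matrix;
#  spectral (transductive): the cached all-subject embedding blocks.
.features_for <- function(spec, X, spectral, structs) {
  if (spec$scheme == "volumetric") X[, structs, drop = FALSE]
  else .spectral_cols(spectral, structs)
}

#' Grid-search training of one classifier
#'
#' Exhaustive search over C x gamma x D scored by leave-one-out accuracy on
#' the training data only; the best combination (ties broken toward smaller
#' D, then smaller C, then smaller gamma) is refit on the full training set.
#' Structure ranking, if not supplied, is computed from the training data.
#'
#' @param X numeric matrix, training subjects x 83 structures
#'   (ICV-normalized volumes)
#' @param labels two-class labels (training subjects, >= 3 per class)
#' @param spec a \code{\link{classifierSpec}}
#' @param ranking optional \linkS4class{StructureRanking} computed on the
#'   training data; computed internally when NULL
#' @param spectral optional \linkS4class{SpectralFeatures} over the same
#'   subjects (required for the spectral scheme)
#' @param positive positive-class label (default: patients / left-focus)
#' @param probability fit Platt-style posteriors on the final model
#' @return classed list \code{TrainedClassifier}: \code{model},
#'   \code{C}, \code{gamma}, \code{D}, \code{structures}, \code{scaling},
#'   \code{loo_accuracy}, \code{positive}, \code{spec}
#' @export
trainWithGrid <- function(X, labels, spec = classifierSpec(),
                          ranking = NULL, spectral = NULL, positive = NULL,
                          probability = FALSE) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2) stop("exactly two classes required")
  if (any(table(labels) < 3)) stop("each class needs >= 3 training members")
  if (spec$scheme == "spectral" && is.null(spectral))
    stop("spectral scheme needs a SpectralFeatures object")
  if (is.null(positive)) positive <- .default_positive(levels(labels))
  if (is.null(ranking))
    ranking <- .rank_matrix_bin(X, labels, spec$sep_params,
                                D = min(max(spec$D_grid), ncol(X)))
  if (spec$scheme == "spectral") {
    # drop ranked structures without an embedding (zero-variance columns)
    keep <- ranking@entries$structure %in% spectral@structures
    ranking@entries <- ranking@entries[keep, , drop = FALSE]
  }
  D_grid <- spec$D_grid[spec$D_grid <= nrow(ranking@entries)]
  if (!length(D_grid)) stop("no admissible D in D_grid")
  gamma_grid <- if (spec$kernel == "linear") spec$gamma_grid[1] else spec$gamma_grid
  best <- NULL
  single <- length(D_grid) * length(spec$C_grid) * length(gamma_grid) == 1
  for (D in D_grid) {
    structs <- utils::head(ranking@entries$structure, D)
    feats <- .features_for(spec, X, spectral, structs)
    sc <- .scale_fit(feats)
    fs <- .scale_apply(feats, sc)
    for (C in spec$C_grid) for (gamma in gamma_grid) {
      acc <- if (single) NA_real_ else
        .loo_accuracy(fs, labels, spec, C, gamma)
      if (is.null(best) || (!single && acc > best$acc))
        best <- list(acc = acc, D = D, C = C, gamma = gamma,
                     structs = structs, sc = sc)
    }
  }
  feats <- .features_for(spec, X, spectral, best$structs)
  fs <- .scale_apply(feats, best$sc)
  model <- e1071::svm(fs, labels, kernel = .svm_kernel(spec), cost = best$C,
                      gamma = best$gamma, scale = FALSE,
                      probability = probability)
  structure(list(model = model, C = best$C, gamma = best$gamma, D = best$D,
                 structures = best$structs, scaling = best$sc,
                 ranking = ranking, loo_accuracy = best$acc,
                 positive = positive, spec = spec),
            class = "TrainedClassifier")
}

# Predict labels (and optionally Platt posteriors of the positive class)
# for new subjects given a subjects x structures matrix (volumetric) or a
# precomputed feature matrix row block (spectral transductive).
.predict_classifier <- function(fit, features, posterior = FALSE) {
  fs <- .scale_apply(features, fit$scaling)
  pred <- stats::predict(fit$model, fs, probability = posterior)
  out <- list(label = as.character(pred))
  if (posterior) {
    pr <- attr(pred, "probabilities")
    out$posterior <- pr[, fit$positive]
  }
  out
}

#' Predict with a trained classifier
#'
#' @param fit a \code{TrainedClassifier} from \code{\link{trainWithGrid}}
#' @param X new subjects x structures matrix (volumetric scheme), or a
#'   \linkS4class{SpectralFeatures} covering the new subjects (spectral)
#' @param posterior also return Platt posteriors of the positive class
#'   (requires \code{probability = TRUE} at training)
#' @return list with \code{label} and optionally \code{posterior}
#' @export
predictClassifier <- function(fit, X, posterior = FALSE) {
  stopifnot(inherits(fit, "TrainedClassifier"))
  features <- if (methods::is(X, "SpectralFeatures"))
    .spectral_cols(X, fit$structures)
  else {
    miss <- setdiff(fit$structures, colnames(X))
    if (length(miss))
      stop("feature-name mismatch: missing ", paste(miss, collapse = ", "))
    X[, fit$structures, drop = FALSE]
  }
  .predict_classifier(fit, features, posterior = posterior)
}

#' Combine two patient posteriors by the maximum rule
#'
#' A subject is labelled patient when the larger of the left-model and
#' right-model patient posteriors strictly exceeds 0.5 (ties at exactly 0.5
#' stay control); the reported posterior is that maximum.
#'
#' @param posterior_L,posterior_R patient posteriors from the side-specific
#'   models, in [0, 1]
#' @return data.frame: \code{posterior} (the max) and \code{label}
#' @export
combinePosteriors <- function(posterior_L, posterior_R) {
  stopifnot(length(posterior_L) == length(posterior_R),
            all(posterior_L >= 0 & posterior_L <= 1),
            all(posterior_R >= 0 & posterior_R <= 1))
  p <- pmax(posterior_L, posterior_R)
  data.frame(posterior = p,
             label = ifelse(p > 0.5, "patient", "control"),
             stringsAsFactors = FALSE)
}

#' Combine side-specific classifiers by maximum posterior
#'
#' Given classifiers trained on left-focus-vs-control and
#' right-focus-vs-control, a subject is labelled patient when the larger of
#' the two patient posteriors strictly exceeds 0.5; the reported posterior
#' is that maximum.
#'
#' @param model_L,model_R \code{TrainedClassifier}s fitted with
#'   \code{probability = TRUE}, positive class = patients
#' @param X subjects x structures matrix (or SpectralFeatures) covering the
#'   features of both models
#' @return data.frame: \code{posterior_L}, \code{posterior_R},
#'   \code{posterior} (the max), \code{label} ("patient" or "control")
#' @export
combineSideClassifiers <- function(model_L, model_R, X) {
  pL <- predictClassifier(model_L, X, posterior = TRUE)$posterior
  pR <- predictClassifier(model_R, X, posterior = TRUE)$posterior
  out <- combinePosteriors(pL, pR)
  cbind(data.frame(posterior_L = pL, posterior_R = pR), out)
}

# Stratified fold assignment: class members dealt round-robin into folds
# after a shuffle; re-drawn (bounded) if any training split loses a class.
.stratified_folds <- function(labels, folds, max_redraw = 100L) {
  n <- length(labels)
  if (folds == n) return(sample(n))  # LOO limit: one subject per fold
  for (try in seq_len(max_redraw)) {
    fold <- integer(n)
    for (lev in levels(labels)) {
      idx <- sample(which(labels == lev))
      fold[idx] <- rep_len(sample(folds), length(idx))
    }
    ok <- all(vapply(seq_len(folds), function(f) {
      tr <- labels[fold != f]
      length(tr) == 0 || nlevels(droplevels(tr)) == 2
    }, TRUE))
    if (ok) return(fold)
  }
  stop("could not draw non-degenerate stratified folds")
}

# Transductive spectral cache over every structure with nonzero variance.
.spectral_cache <- function(X, spec) {
  ok <- apply(X, 2, function(v) stats::sd(v) > 0)
  sf <- NULL
  cohort_like <- colnames(X)[ok]
  # build directly (X is subjects x structures, already normalized ratios)
  blocks <- lapply(cohort_like, function(s) {
    z <- zscoreVolumes(X[, s], structure = s)
    L <- graphLaplacian(similarityMatrix(z, c = spec$c),
                        variant = spec$laplacian)
    V <- spectralEmbed(L, spec$k)
    colnames(V) <- paste0(s, ".ev", seq_len(spec$k))
    V
  })
  M <- do.call(cbind, blocks)
  rownames(M) <- rownames(X)
  methods::new("SpectralFeatures", matrix = M, structures = cohort_like,
               k = spec$k, c = spec$c, laplacianVariant = spec$laplacian)
}

# Train-only spectral features with Nystrom extension of the test rows.
.spectral_nystrom <- function(X, train, test, structs, spec) {
  blocks_tr <- list(); blocks_te <- list()
  for (s in structs) {
    zt <- zscoreVolumes(X[train, s], structure = s)
    mu <- mean(X[train, s])
    sdv <- sqrt(mean((X[train, s] - mu)^2))
    zn <- (X[test, s] - mu) / sdv
    L <- graphLaplacian(similarityMatrix(zt, c = spec$c),
                        variant = spec$laplacian)
    es <- eigen(L, symmetric = TRUE)
    idx <- seq(length(zt), length(zt) - spec$k + 1)
    V <- es$vectors[, idx, drop = FALSE]
    lam <- es$values[idx]
    for (j in seq_len(spec$k)) {
      i <- which.max(abs(V[, j]))
      if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    Vn <- .nystrom_extend(zt, zn, V, lam, c = spec$c)
    colnames(V) <- colnames(Vn) <- paste0(s, ".ev", seq_len(spec$k))
    blocks_tr[[s]] <- V; blocks_te[[s]] <- Vn
  }
  list(train = do.call(cbind, blocks_tr), test = do.call(cbind, blocks_te))
}

#' Repeated stratified k-fold evaluation of a classification scheme
#'
#' Per repeat, subjects are dealt into stratified folds; per fold, structure
#' ranking (and the grid search over C, gamma, D) uses the training split
#' only, the winning model is refit and the held-out fold predicted.
#' Accuracy, sensitivity and specificity are computed per repeat and
#' summarized as mean +/- SD. Fully seeded and reproducible.
#'
#' @param cohort a normalized \linkS4class{TleCohort} containing exactly the
#'   subjects of the experiment
#' @param labels two-class labels in cohort order
#' @param spec a \code{\link{classifierSpec}}
#' @param folds folds per repeat (default 10; 5 is used for n = 20 designs)
#' @param repeats number of independent repeats (default 10)
#' @param seed integer seed controlling fold draws
#' @param positive positive-class label (default: patients / left-focus)
#' @return a classed list \code{cvReport}: per-repeat metrics, means, SDs,
#'   chosen hyperparameters per fold, fold assignments, per-subject
#'   predictions, and a selection log (training indices seen by ranking in
#'   every fold)
#' @export
evaluateRepeatedKfold <- function(cohort, labels, spec = classifierSpec(),
                                  folds = 10L, repeats = 10L, seed = 1L,
                                  positive = NULL) {
  stopifnot(methods::is(cohort, "TleCohort"))
  if (!isNormalized(cohort)) stop("cohort must be ICV-normalized")
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2) stop("exactly two classes required")
  if (is.null(positive)) positive <- .default_positive(levels(labels))
  negative <- setdiff(levels(labels), positive)
  X <- t(volumes(cohort))
  n <- nrow(X)
  spectral <- if (spec$scheme == "spectral" && spec$embed == "transductive")
    .spectral_cache(X, spec) else NULL
  per_repeat <- vector("list", repeats)
  fold_assign <- matrix(NA_integer_, repeats, n,
                        dimnames = list(NULL, rownames(X)))
  chosen <- list(); sel_log <- list()
  predictions <- matrix(NA_character_, repeats, n,
                        dimnames = list(NULL, rownames(X)))
  withr::with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold <- .stratified_folds(labels, folds)
      fold_assign[r, ] <- fold
      for (f in sort(unique(fold))) {
        train <- which(fold != f); test <- which(fold == f)
        if (!length(test)) next
        ranking <- .rank_matrix_bin(X[train, , drop = FALSE], labels[train],
                                    spec$sep_params,
                                    D = min(max(spec$D_grid), ncol(X)))
        sel_log[[length(sel_log) + 1L]] <- list(
          repeat_ = r, fold = f, train_idx = train,
          labels_seen = as.character(labels[train]))
        if (spec$scheme == "spectral" && spec$embed == "nystrom") {
          fit <- trainWithGrid(X[train, , drop = FALSE], labels[train], spec,
                               ranking = ranking,
                               spectral = .nystrom_trainer(X, train, ranking, spec),
                               positive = positive)
          ny <- .spectral_nystrom(X, train, test, fit$structures, spec)
          pred <- .predict_classifier(fit, ny$test)$label
        } else if (spec$scheme == "spectral") {
          fit <- trainWithGrid(.subset_rows(X, train), labels[train], spec,
                               ranking = ranking,
                               spectral = .subset_spectral(spectral, train),
                               positive = positive)
          pred <- .predict_classifier(
            fit, .spectral_cols(.subset_spectral(spectral, test),
                                fit$structures))$label
        } else {
          fit <- trainWithGrid(X[train, , drop = FALSE], labels[train], spec,
                               ranking = ranking, positive = positive)
          pred <- predictClassifier(fit, X[test, , drop = FALSE])$label
        }
        predictions[r, test] <- pred
        chosen[[length(chosen) + 1L]] <- data.frame(
          repeat_ = r, fold = f, D = fit$D, C = fit$C, gamma = fit$gamma)
      }
      truth <- labels
      pred_r <- factor(predictions[r, ], levels = levels(labels))
      tp <- sum(pred_r == positive & truth == positive)
      fn <- sum(pred_r != positive & truth == positive)
      tn <- sum(pred_r == negative & truth == negative)
      fp <- sum(pred_r != negative & truth == negative)
      per_repeat[[r]] <- metricsFromConfusion(tp, fn, tn, fp)
    }
  })
  met <- do.call(rbind, per_repeat)
  structure(list(
    scheme = spec$scheme, folds = folds, repeats = repeats,
    positive = positive, per_repeat = as.data.frame(met),
    mean = colMeans(met), sd = apply(met, 2, stats::sd),
    chosen = do.call(rbind, chosen), fold_assignments = fold_assign,
    predictions = predictions, selection_log = sel_log, seed = seed),
    class = "cvReport")
}

# helpers kept tiny so the spectral fold paths above stay readable
.subset_rows <- function(X, idx) X[idx, , drop = FALSE]
.subset_spectral <- function(sf, idx) {
  methods::new("SpectralFeatures", matrix = sf@matrix[idx, , drop = FALSE],
               structures = sf@structures, k = sf@k, c = sf@c,
               laplacianVariant = sf@laplacianVariant)
}
# for the nystrom grid search the training features are train-only
.nystrom_trainer <- function(X, train, ranking, spec) {
  structs <- ranking@entries$structure
  sdv <- apply(X[train, structs, drop = FALSE], 2, stats::sd)
  structs <- structs[sdv > 0]
  ny <- .spectral_nystrom(X, train, integer(0), structs, spec)
  methods::new("SpectralFeatures", matrix = ny$train, structures = structs,
               k = spec$k, c = spec$c, laplacianVariant = spec$laplacian)
}

#' @export
print.cvReport <- function(x, ...) {
  cat(sprintf("cvReport (%s scheme): %d-fold CV x %d repeats\n",
              x$scheme, x$folds, x$repeats))
  cat(sprintf("  accuracy    %.1f +/- %.1f %%\n", x$mean["accuracy"],
              x$sd["accuracy"]))
  cat(sprintf("  sensitivity %.1f +/- %.1f %%\n", x$mean["sensitivity"],
              x$sd["sensitivity"]))
  cat(sprintf("  specificity %.1f +/- %.1f %%\n", x$mean["specificity"],
              x$sd["specificity"]))
  invisible(x)
}

#' Permutation test of classification accuracy
#'
#' Shuffles the clinical labels, re-runs structure ranking on the permuted
#' labels, and carries out a full leave-one-out cross-validation of an SVM
#' on the top-ranked structures, recording the permuted accuracy; repeated
#' \code{n_permutations} times to estimate the null distribution. The
#' observed accuracy is computed by the identical procedure on the
#' unpermuted labels. \eqn{p = (1 + \#\{null \ge observed\}) /
#' (1 + n_{perm})}; the statistic is the observed accuracy standardized
#' against the null mean and SD. Hyperparameters are the first grid values
#' of C, gamma and D (no nested grid search inside permutations).
#'
#' @param cohort a normalized \linkS4class{TleCohort}
#' @param labels two-class labels in cohort order
#' @param spec a \code{\link{classifierSpec}}
#' @param n_permutations number of label permutations (>= 99)
#' @param seed integer seed
#' @param log_selection keep, per permutation, the label vector that the
#'   ranking saw (for leakage instrumentation; default FALSE)
#' @return classed list \code{PermutationResult}: \code{observed},
#'   \code{null}, \code{p_value}, \code{statistic}, \code{n_permutations}
#' @export
permutationTest <- function(cohort, labels, spec = classifierSpec(),
                            n_permutations = 1000L, seed = 1L,
                            log_selection = FALSE) {
  stopifnot(methods::is(cohort, "TleCohort"))
  if (!isNormalized(cohort)) stop("cohort must be ICV-normalized")
  if (n_permutations < 99) stop("n_permutations must be >= 99")
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2) stop("exactly two classes required")
  X <- t(volumes(cohort))
  D <- min(spec$D_grid[1], ncol(X))
  C <- spec$C_grid[1]
  gamma <- spec$gamma_grid[1]
  # label-free precomputation: z-scored columns and their kernel matrices
  ok <- which(apply(X, 2, function(v) stats::sd(v) > 0))
  Z <- scale(X[, ok, drop = FALSE])
  Ks <- lapply(seq_along(ok), function(j)
    .kernel_matrix(Z[, j], spec$sep_params))
  spectral_all <- if (spec$scheme == "spectral")
    .spectral_cache(X, spec) else NULL
  loo_for <- function(lab) {
    J <- vapply(Ks, .J_from_kernel, 0, labels = lab,
                epsilon = spec$sep_params$epsilon)
    top <- colnames(Z)[order(-J, seq_along(J))][seq_len(D)]
    feats <- if (spec$scheme == "spectral")
      .spectral_cols(spectral_all, top) else X[, top, drop = FALSE]
    fs <- .scale_apply(feats, .scale_fit(feats))
    list(acc = .loo_accuracy(fs, lab, spec, C, gamma), top = top)
  }
  observed <- loo_for(labels)$acc
  sel_log <- if (log_selection) vector("list", n_permutations) else NULL
  null_acc <- numeric(n_permutations)
  withr::with_seed(seed, {
    for (p in seq_len(n_permutations)) {
      perm <- sample(labels)
      res <- loo_for(perm)
      null_acc[p] <- res$acc
      if (log_selection)
        sel_log[[p]] <- list(labels_seen = as.character(perm),
                             selected = res$top)
    }
  })
  p_value <- (1 + sum(null_acc >= observed)) / (1 + n_permutations)
  statistic <- (observed - mean(null_acc)) / stats::sd(null_acc)
  structure(list(n_permutations = n_permutations, null = null_acc,
                 observed = observed, p_value = p_value,
                 statistic = statistic, D = D, C = C, gamma = gamma,
                 selection_log = sel_log, seed = seed),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf(
    "PermutationResult: observed %.1f%%, null %.1f +/- %.1f%% (%d perms)\n",
    x$observed, mean(x$null), stats::sd(x$null), x$n_permutations))
  cat(sprintf("  p = %.4g, standardized statistic = %.3f\n",
              x$p_value, x$statistic))
  invisible(x)
}
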