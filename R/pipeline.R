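# Experiment orchestration: the five two-class experiments, cohort
# descriptive statistics, and report assembly.

.experiment_classes <- list(
  exp1 = c("TLE-HA", "control"),
  exp2 = c("TLE-HA_R", "TLE-HA_L"),
  exp3 = c("TLE-HA", "TLE-N"),
  exp4 = c("TLE-N", "control"),
  exp5 = c("TLE-N_R", "TLE-N_L"))

# Map raw group labels to experiment class labels ("TLE-HA" pools _L/_R).
.class_of <- function(group, class_label) {
  if (class_label %in% c("TLE-HA", "TLE-N"))
    ifelse(sub("_[LR]$", "", group) == class_label, class_label, NA)
  else ifelse(group == class_label, class_label, NA)
}

#' Configure one classification experiment
#'
#' The five standard experiments: exp1 TLE-HA vs control, exp2 TLE-HA_R vs
#' TLE-HA_L (lateralization), exp3 TLE-HA vs TLE-N, exp4 TLE-N vs control,
#' exp5 TLE-N_R vs TLE-N_L (lateralization). Pooled labels "TLE-HA" /
#' "TLE-N" collect both focus sides.
#'
#' @param experiment "exp1".."exp5"
#' @param cohort the cohort source: a \linkS4class{TleCohort}, a
#'   \code{\link{cohortConfig}} to generate from, or a file path readable by
#'   \code{\link{readCohort}}; default generates the study-sized synthetic
#'   cohort
#' @param schemes which classification schemes to run
#' @param folds CV folds; \code{NULL} picks 5 when the experiment has <= 20
#'   subjects and 10 otherwise
#' @param repeats CV repeats (default 10)
#' @param n_permutations permutations for the significance test
#' @param seed integer master seed
#' @param volumetric_spec,spectral_spec \code{\link{classifierSpec}}s;
#'   defaults use modest grids suitable for desk-scale cohorts
#' @return classed list \code{ExperimentConfig}
#' @export
experimentConfig <- function(experiment = c("exp1", "exp2", "exp3", "exp4", "exp5"),
                             cohort = NULL, schemes = c("volumetric", "spectral"),
                             folds = NULL, repeats = 10L,
                             n_permutations = 500L, seed = 1L,
                             volumetric_spec = classifierSpec(
                               "volumetric", C_grid = c(1, 64),
                               gamma_grid = c(2^-7, 2^-3), D_grid = c(2, 6)),
                             spectral_spec = classifierSpec(
                               "spectral", C_grid = c(1, 64),
                               D_grid = c(2, 6))) {
  experiment <- match.arg(experiment)
  schemes <- match.arg(schemes, several.ok = TRUE)
  if (is.null(cohort)) cohort <- defaultCohortConfig(seed = seed)
  structure(list(experiment = experiment,
                 class_a = .experiment_classes[[experiment]][1],
                 class_b = .experiment_classes[[experiment]][2],
                 cohort = cohort, schemes = schemes, folds = folds,
                 repeats = as.integer(repeats),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 volumetric_spec = volumetric_spec,
                 spectral_spec = spectral_spec),
            class = "ExperimentConfig")
}

.resolve_cohort <- function(src) {
  if (methods::is(src, "TleCohort")) src
  else if (inherits(src, "CohortConfig")) generateCohort(src)
  else if (is.character(src) && length(src) == 1) readCohort(src)
  else stop("cohort must be a TleCohort, a CohortConfig, or a file path")
}

#' Run one experiment end to end
#'
#' Generates or loads the cohort, ICV-normalizes it, subsets to the two
#' classes, ranks structures (descriptive, over the experiment cohort),
#' evaluates the requested classification schemes by repeated stratified
#' k-fold CV, runs a permutation test per scheme, and assembles cohort
#' statistics into a reproducible report. Every number in the report is
#' recomputable from the configuration and seed.
#'
#' @param config an \code{\link{experimentConfig}}
#' @return classed list \code{ExperimentReport}: config echo, cohort
#'   statistics, \linkS4class{StructureRanking}, a \code{cvReport} and
#'   \code{PermutationResult} per scheme, package version and seed
#' @export
runExperiment <- function(config) {
  stopifnot(inherits(config, "ExperimentConfig"))
  cohort <- .resolve_cohort(config$cohort)
  raw <- if (isNormalized(cohort)) NULL else cohort
  if (!isNormalized(cohort)) cohort <- normalizeByIcv(cohort)
  groups <- subjectData(cohort)$group
  lab_a <- .class_of(groups, config$class_a)
  lab_b <- .class_of(groups, config$class_b)
  keep <- !is.na(lab_a) | !is.na(lab_b)
  if (!any(!is.na(lab_a)) || !any(!is.na(lab_b)))
    stop("cohort lacks one of the classes ", config$class_a, " / ",
         config$class_b)
  sub <- cohort[, keep]
  labels <- factor(ifelse(!is.na(lab_a[keep]), config$class_a, config$class_b),
                   levels = c(config$class_a, config$class_b))
  n <- ncol(sub)
  folds <- if (is.null(config$folds)) (if (n <= 20) 5L else 10L)
           else as.integer(config$folds)
  ranking <- rankStructuresBin(sub, labels,
                               params = config$volumetric_spec$sep_params,
                               D = max(config$volumetric_spec$D_grid))
  cv <- list(); perm <- list()
  for (sc in config$schemes) {
    spec <- if (sc == "volumetric") config$volumetric_spec
            else config$spectral_spec
    cv[[sc]] <- evaluateRepeatedKfold(sub, labels, spec, folds = folds,
                                      repeats = config$repeats,
                                      seed = config$seed)
    perm[[sc]] <- permutationTest(sub, labels, spec,
                                  n_permutations = config$n_permutations,
                                  seed = config$seed + 1L)
  }
  stats_block <- cohortStatistics(if (is.null(raw)) cohort else raw)
  structure(list(
    config = config, experiment = config$experiment, n = n,
    labels = table(labels), ranking = ranking, cv = cv, permutation = perm,
    cohort_statistics = stats_block,
    version = as.character(utils::packageVersion("tleMorph")),
    seed = config$seed), class = "ExperimentReport")
}

#' @export
print.ExperimentReport <- function(x, ...) {
  cat("ExperimentReport:", x$experiment, "-",
      x$config$class_a, "vs", x$config$class_b,
      sprintf("(n = %d)\n", x$n))
  cat("  top structures:",
      paste(utils::head(x$ranking@entries$structure, 3), collapse = ", "),
      "\n")
  for (sc in names(x$cv)) {
    cat(sprintf("  %s: accuracy %.1f +/- %.1f %%, permutation p = %.4g\n",
                sc, x$cv[[sc]]$mean["accuracy"], x$cv[[sc]]$sd["accuracy"],
                x$permutation[[sc]]$p_value))
  }
  invisible(x)
}

#' Serialize an experiment report
#'
#' Writes \code{report.json} (summary numbers) and
#' \code{predictions_<scheme>.tsv} (per-repeat per-subject predictions)
#' into \code{dir}.
#'
#' @param report an \code{ExperimentReport}
#' @param dir output directory (created if needed)
#' @return invisibly, the JSON path
#' @export
writeExperimentReport <- function(report, dir) {
  stopifnot(inherits(report, "ExperimentReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  js <- list(
    experiment = report$experiment,
    class_a = report$config$class_a, class_b = report$config$class_b,
    n = report$n, seed = report$seed, version = report$version,
    ranking = list(structure = report$ranking@entries$structure,
                   J = report$ranking@entries$J),
    cv = lapply(report$cv, function(r)
      list(mean = as.list(r$mean), sd = as.list(r$sd),
           folds = r$folds, repeats = r$repeats)),
    permutation = lapply(report$permutation, function(p)
      list(observed = p$observed, p_value = p$p_value,
           statistic = p$statistic, n_permutations = p$n_permutations)))
  path <- file.path(dir, "report.json")
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (sc in names(report$cv)) {
    utils::write.table(
      report$cv[[sc]]$predictions,
      file.path(dir, paste0("predictions_", sc, ".tsv")),
      sep = "\t", quote = FALSE, col.names = NA)
  }
  invisible(path)
}

#' Cohort descriptive statistics
#'
#' Per group: n, median (range) age, sex counts, ICV mean +/- SD with a
#' Welch t-test against the reference group, a Mann-Whitney U test on ages
#' (normal approximation with ties correction), the Pearson correlation of
#' mean bilateral hippocampal volume with ICV, and per-structure
#' coefficients of variation (SD/mean). Expects raw (mm^3) volumes for the
#' hippocampus-ICV correlation to be on the natural scale; it is computed
#' on whatever volumes the cohort carries.
#'
#' @param cohort a \linkS4class{TleCohort}
#' @param reference reference group label for the two-sample tests
#' @return classed list \code{CohortStatistics}
#' @export
cohortStatistics <- function(cohort, reference = "control") {
  stopifnot(methods::is(cohort, "TleCohort"))
  cd <- as.data.frame(subjectData(cohort))
  V <- volumes(cohort)
  hip <- colMeans(V[c("Hippocampus_L", "Hippocampus_R"), , drop = FALSE])
  groups <- unique(cd$group)
  ref_icv <- cd$icv_cm3[cd$group == reference]
  ref_age <- cd$age[cd$group == reference]
  per_group <- lapply(groups, function(g) {
    i <- cd$group == g
    n <- sum(i)
    out <- list(
      group = g, n = n,
      age_median = stats::median(cd$age[i]),
      age_range = range(cd$age[i]),
      n_female = sum(cd$sex[i] == "F"),
      icv_mean = mean(cd$icv_cm3[i]), icv_sd = stats::sd(cd$icv_cm3[i]))
    if (g != reference && length(ref_icv) >= 2 && n >= 2) {
      out$icv_t_p <- stats::t.test(cd$icv_cm3[i], ref_icv)$p.value
      out$age_u_p <- stats::wilcox.test(cd$age[i], ref_age,
                                        exact = FALSE, correct = TRUE)$p.value
    }
    if (n >= 3 && stats::sd(hip[i]) > 0 && stats::sd(cd$icv_cm3[i]) > 0) {
      ct <- stats::cor.test(hip[i], cd$icv_cm3[i])
      out$hippocampus_icv_r <- unname(ct$estimate)
      out$hippocampus_icv_p <- ct$p.value
    }
    cv <- apply(V[, i, drop = FALSE], 1, function(v)
      if (mean(v) > 0) stats::sd(v) / mean(v) else NA_real_)
    out$volume_cv <- cv
    out
  })
  names(per_group) <- groups
  structure(list(reference = reference, groups = per_group),
            class = "CohortStatistics")
}

#' @export
print.CohortStatistics <- function(x, ...) {
  cat("CohortStatistics (reference:", x$reference, ")\n")
  for (g in x$groups) {
    cat(sprintf(
      "  %-10s n=%3d  age %d (%d-%d)  F=%d  ICV %.0f +/- %.0f cm^3%s\n",
      g$group, g$n, g$age_median, g$age_range[1], g$age_range[2],
      g$n_female, g$icv_mean, g$icv_sd,
      if (!is.null(g$icv_t_p)) sprintf("  (t-test p=%.3f)", g$icv_t_p) else ""))
  }
  invisible(x)
}
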