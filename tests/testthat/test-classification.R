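test_that("confusion metrics match closed-form arithmetic", {
  m <- metricsFromConfusion(60, 0, 26, 2)
  expect_equal(unname(m["sensitivity"]), 100)
  expect_equal(unname(m["specificity"]), 100 * 26 / 28, tolerance = 1e-9)
  expect_equal(unname(m["accuracy"]), 100 * 86 / 88, tolerance = 1e-9)
  expect_equal(unname(metricsFromConfusion(10, 0, 10, 0)),
               c(100, 100, 100))
  expect_equal(unname(metricsFromConfusion(0, 10, 0, 10)), c(0, 0, 0))
  # undefined metrics are flagged, not zeroed
  expect_warning(m2 <- metricsFromConfusion(0, 0, 5, 5), "sensitivity")
  expect_true(is.na(m2["sensitivity"]))
  expect_equal(unname(m2["accuracy"]), 50)
})

test_that("posterior combination follows the strict max rule", {
  r <- combinePosteriors(c(0.1, 0.9, 0.5), c(0.1, 0.2, 0.5))
  expect_equal(r$label, c("control", "patient", "control"))
  expect_equal(r$posterior, c(0.1, 0.9, 0.5))
})

test_that("grid search separates well-separated clusters and refits", {
  set.seed(9)
  # clusters +/- 5 SD apart on two structures, noise elsewhere
  n <- 10
  X <- matrix(rnorm(2 * n * 83), 2 * n, 83,
              dimnames = list(NULL, structureNames()))
  X[, "Hippocampus_L"] <- c(rnorm(n, -5), rnorm(n, 5))
  lab <- factor(rep(c("patient", "control"), each = n))
  spec <- fast_vol_spec()
  fit <- trainWithGrid(X, lab, spec)
  expect_equal(fit$structures[1], "Hippocampus_L")
  expect_equal(fit$loo_accuracy, 100)
  # held-out points from either cluster are classified correctly
  held <- matrix(0, 2, 83, dimnames = list(NULL, structureNames()))
  held[, "Hippocampus_L"] <- c(-5, 5)
  expect_equal(predictClassifier(fit, held)$label, c("patient", "control"))
})

test_that("grid-search ties break toward smaller D, then C, then gamma", {
  set.seed(10)
  X <- matrix(rnorm(20 * 83), 20, 83,
              dimnames = list(NULL, structureNames()))
  X[, "Hippocampus_L"] <- rep(c(-5, 5), each = 10)
  lab <- factor(rep(c("a", "b"), each = 10))
  # all grid points reach 100% LOO -> first (smallest) combination wins
  spec <- classifierSpec("volumetric", C_grid = c(1, 4),
                         gamma_grid = c(0.25, 1), D_grid = c(1, 2))
  fit <- trainWithGrid(X, lab, spec)
  expect_equal(fit$D, 1)
  expect_equal(fit$C, 1)
  expect_equal(fit$gamma, 0.25)
  # degenerate singleton grid short-circuits
  s1 <- classifierSpec("volumetric", C_grid = 1, gamma_grid = 1, D_grid = 1)
  expect_equal(trainWithGrid(X, lab, s1)$D, 1)
  expect_error(trainWithGrid(X[1:5, ], factor(c("a", "a", "b", "b", "b"))),
               ">= 3")
})

test_that("repeated k-fold evaluation is seeded, stratified and consistent", {
  coh <- normalizeByIcv(make_two_group_cohort(n_patient = 16, n_control = 14,
                                              seed = 2))
  lab <- two_class_labels(coh)
  spec <- classifierSpec("volumetric", C_grid = 1, gamma_grid = 0.25,
                         D_grid = 2)
  a <- evaluateRepeatedKfold(coh, lab, spec, folds = 5, repeats = 3, seed = 7)
  b <- evaluateRepeatedKfold(coh, lab, spec, folds = 5, repeats = 3, seed = 7)
  expect_identical(a$fold_assignments, b$fold_assignments)
  expect_identical(a$per_repeat, b$per_repeat)
  # patients are the positive class by default
  expect_equal(a$positive, "TLE-HA_L")
  # accuracy is consistent with sensitivity/specificity and class sizes
  n_pos <- sum(lab == "TLE-HA_L"); n_neg <- sum(lab == "control")
  recomputed <- (a$per_repeat$sensitivity * n_pos +
                 a$per_repeat$specificity * n_neg) / (n_pos + n_neg)
  expect_equal(a$per_repeat$accuracy, recomputed, tolerance = 1e-9)
  # every subject predicted exactly once per repeat
  expect_false(any(is.na(a$predictions)))
})

test_that("folds = n reduces to leave-one-out", {
  coh <- normalizeByIcv(make_two_group_cohort(n_patient = 6, n_control = 6,
                                              seed = 4))
  lab <- two_class_labels(coh)
  spec <- classifierSpec("volumetric", C_grid = 1, gamma_grid = 0.25,
                         D_grid = 1)
  r <- evaluateRepeatedKfold(coh, lab, spec, folds = ncol(coh), repeats = 1,
                             seed = 3)
  # each fold holds exactly one subject
  expect_equal(sort(as.integer(r$fold_assignments[1, ])), 1:ncol(coh))
})

test_that("spectral scheme evaluates in both embedding modes", {
  coh <- normalizeByIcv(make_two_group_cohort(n_patient = 12, n_control = 12,
                                              seed = 5))
  lab <- two_class_labels(coh)
  tr <- evaluateRepeatedKfold(coh, lab,
                              classifierSpec("spectral", C_grid = 1, D_grid = 1),
                              folds = 4, repeats = 2, seed = 1)
  ny <- evaluateRepeatedKfold(coh, lab,
                              classifierSpec("spectral", C_grid = 1, D_grid = 1,
                                             embed = "nystrom"),
                              folds = 4, repeats = 2, seed = 1)
  # a 0.30 hippocampal reduction is nearly perfectly separable either way
  expect_gte(tr$mean[["accuracy"]], 90)
  expect_gte(ny$mean[["accuracy"]], 80)
})

test_that("permutation p-value follows the add-one formula", {
  coh <- normalizeByIcv(make_two_group_cohort(n_patient = 12, n_control = 12,
                                              effects = c(Hippocampus_L = 0.4),
                                              noise_cv = 0.05, seed = 6))
  lab <- two_class_labels(coh)
  spec <- classifierSpec("volumetric", C_grid = 1, gamma_grid = 0.25,
                         D_grid = 1)
  pt <- permutationTest(coh, lab, spec, n_permutations = 99, seed = 2)
  expect_equal(pt$p_value,
               (1 + sum(pt$null >= pt$observed)) / (1 + 99))
  # the planted effect separates perfectly: observed beats every null draw
  expect_true(pt$observed > max(pt$null))
  expect_equal(pt$p_value, 1 / 100)
  expect_gt(pt$statistic, 2)
  expect_error(permutationTest(coh, lab, spec, n_permutations = 50), ">= 99")
})

test_that("side-specific classifiers combine into one patient decision", {
  coh <- normalizeByIcv(generateCohort(defaultCohortConfig(seed = 13)))
  g <- subjectData(coh)$group
  X <- t(volumes(coh))
  spec <- classifierSpec("volumetric", C_grid = 4, gamma_grid = 0.25,
                         D_grid = 2)
  iL <- g %in% c("TLE-HA_L", "control")
  iR <- g %in% c("TLE-HA_R", "control")
  mL <- trainWithGrid(X[iL, ], droplevels(factor(g[iL])), spec,
                      positive = "TLE-HA_L", probability = TRUE)
  mR <- trainWithGrid(X[iR, ], droplevels(factor(g[iR])), spec,
                      positive = "TLE-HA_R", probability = TRUE)
  res <- combineSideClassifiers(mL, mR, X)
  expect_equal(nrow(res), ncol(coh))
  # most patients are flagged, most controls are not
  expect_gt(mean(res$label[grepl("TLE-HA", g)] == "patient"), 0.8)
  expect_gt(mean(res$label[g == "control"] == "control"), 0.6)
  # feature-name mismatch is an error
  absent <- setdiff(colnames(X), mL$structures)[1:10]
  expect_error(predictClassifier(mL, X[, absent]), "mismatch")
})
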