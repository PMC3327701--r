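# Independent oracle: explicit Fisher-style ratio (difference of class
# means squared over summed within-class *population* variances), which the
# linear-kernel criterion must reproduce.
fisher_ratio <- function(x, lab, eps = 1e-8) {
  a <- x[lab == levels(lab)[1]]; b <- x[lab == levels(lab)[2]]
  popvar <- function(v) mean((v - mean(v))^2)
  (mean(a) - mean(b))^2 / (popvar(a) + popvar(b) + eps)
}

test_that("linear-kernel criterion matches the hand-computed worked case", {
  lab <- factor(rep(c("a", "b"), each = 3))
  J <- kernelSeparability(c(1, 2, 3, 7, 8, 9), lab,
                          separabilityParams("linear"))
  # between = (2-8)^2 = 36, within = 2/3 + 2/3
  expect_equal(J, 36 / (4 / 3 + 1e-8), tolerance = 1e-12)
})

test_that("identical class distributions give J = 0", {
  lab <- factor(rep(c("a", "b"), each = 4))
  x <- c(1, 2, 3, 4, 1, 2, 3, 4)
  expect_equal(kernelSeparability(x, lab, separabilityParams("linear")), 0)
  expect_equal(kernelSeparability(x, lab, separabilityParams("gaussian",
                                                             sigma = 1)), 0)
})

test_that("internally constant classes give the epsilon-limited J", {
  lab <- factor(rep(c("a", "b"), each = 3))
  x <- c(0, 0, 0, 1, 1, 1)
  p <- separabilityParams("gaussian", sigma = 1, epsilon = 1e-8)
  J <- kernelSeparability(x, lab, p)
  # within = 0, so J = between / epsilon: large but finite
  expect_true(is.finite(J))
  between <- 1 + 1 - 2 * exp(-1 / 2)  # A + B - 2C at sigma = 1
  expect_equal(J, between / 1e-8, tolerance = 1e-9)
})

test_that("linear-kernel J equals the Fisher ratio on random instances", {
  set.seed(101)
  for (i in 1:50) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    x <- c(rnorm(n1, 0, runif(1, 0.5, 2)), rnorm(n2, runif(1, -2, 2)))
    lab <- factor(rep(c("a", "b"), c(n1, n2)))
    J <- kernelSeparability(x, lab, separabilityParams("linear"))
    expect_equal(J, fisher_ratio(x, lab), tolerance = 1e-10)
  }
})

test_that("J with the median-heuristic bandwidth is affine invariant", {
  set.seed(7)
  x <- c(rnorm(10), rnorm(8, 2))
  lab <- factor(rep(c("a", "b"), c(10, 8)))
  p <- separabilityParams("gaussian")  # sigma = NULL -> median heuristic
  J0 <- kernelSeparability(x, lab, p)
  expect_equal(kernelSeparability(3.7 * x - 11, lab, p), J0, tolerance = 1e-12)
  expect_equal(kernelSeparability(-0.2 * x + 5, lab, p), J0, tolerance = 1e-12)
})

test_that("criterion rejects degenerate inputs", {
  expect_error(kernelSeparability(1:4, factor(c("a", "a", "a", "b"))),
               ">= 2 members")
  expect_error(kernelSeparability(1:4, factor(rep("a", 4))), "two classes")
  expect_error(kernelSeparability(c(1, NA, 3, 4),
                                  factor(rep(c("a", "b"), 2))), "finite")
})

test_that("BIN ranks a single planted structure first", {
  firsts <- vapply(1:20, function(s) {
    coh <- make_two_group_cohort(n_patient = 30, n_control = 28,
                                 effects = c(Hippocampus_L = 0.30), seed = s)
    rk <- rankStructuresBin(normalizeByIcv(coh), two_class_labels(coh), D = 1)
    selectedStructures(rk)[1]
  }, "")
  expect_true(all(firsts == "Hippocampus_L"))
})

test_that("with permuted labels the top J is typical of the null", {
  coh <- make_two_group_cohort(n_patient = 15, n_control = 15,
                               effects = c(Hippocampus_L = 0.30), seed = 5)
  nm <- normalizeByIcv(coh)
  set.seed(42)
  shuffled <- sample(two_class_labels(coh))
  obs <- max(criterionValues(rankStructuresBin(nm, shuffled, D = 1)))
  null_max <- vapply(1:200, function(i)
    max(criterionValues(rankStructuresBin(nm, sample(shuffled), D = 1))), 0)
  p <- mean(null_max >= obs)
  expect_gt(p, 0.01)  # shuffled observation is not an outlier of its null
})

test_that("ranking is deterministic, catalog-tie-broken and guarded", {
  coh <- normalizeByIcv(make_two_group_cohort(n_patient = 6, n_control = 6,
                                              seed = 3))
  lab <- two_class_labels(coh)
  r1 <- rankStructuresBin(coh, lab, D = 5)
  r2 <- rankStructuresBin(coh, lab, D = 5)
  expect_identical(r1@entries$structure, r2@entries$structure)
  expect_identical(criterionValues(r1), criterionValues(r2))
  expect_error(rankStructuresBin(coh, lab, D = 84), "exceeds")
  expect_error(rankStructuresBin(
    make_two_group_cohort(n_patient = 6, n_control = 6, seed = 3), lab, D = 2),
    "normalized")
  # J values are sorted non-increasing
  expect_false(is.unsorted(rev(r1@entries$J)))
})
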