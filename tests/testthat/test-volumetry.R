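test_that("grey-matter masking follows the strict 50% rule with exemptions", {
  lab <- make_region_volume(10, region = "Hippocampus_L")
  gm1 <- array(1, dim = dim(lab@grid))
  gm04 <- array(0.4, dim = dim(lab@grid))
  expect_equal(regionalVolumes(lab, gm1)[["Hippocampus_L"]], 10)
  # below threshold, non-exempt region vanishes
  expect_equal(regionalVolumes(lab, gm04)[["Hippocampus_L"]], 0)
  # exactly 0.5 is excluded (strict threshold)
  gm05 <- array(0.5, dim = dim(lab@grid))
  expect_equal(regionalVolumes(lab, gm05)[["Hippocampus_L"]], 0)
  # exempt structure keeps its full volume regardless of GM probability
  th <- make_region_volume(10, region = "Thalamus_L")
  expect_equal(regionalVolumes(th, gm04)[["Thalamus_L"]], 10)
  # voxel volume scales the result
  big <- make_region_volume(10, region = "Hippocampus_L",
                            voxel_dims = c(2, 1, 1.5))
  expect_equal(regionalVolumes(big, gm1)[["Hippocampus_L"]], 30)
})

test_that("regional volumes are additive over voxel splits", {
  g <- array(0L, dim = c(6, 6, 6))
  g[1:20] <- 1L
  gm <- array(runif(length(g)), dim = dim(g))
  whole <- LabelVolume(g, codes = c("1" = "FusiformG_L"))
  g1 <- g; g1[11:20] <- 0L
  g2 <- g; g2[1:10] <- 0L
  a <- regionalVolumes(LabelVolume(g1, codes = c("1" = "FusiformG_L")), gm)
  b <- regionalVolumes(LabelVolume(g2, codes = c("1" = "FusiformG_L")), gm)
  expect_equal(a[["FusiformG_L"]] + b[["FusiformG_L"]],
               regionalVolumes(whole, gm)[["FusiformG_L"]])
})

test_that("regionalVolumes validates inputs", {
  lab <- make_region_volume(10)
  expect_error(regionalVolumes(lab, array(1, dim = c(2, 2, 2))), "differ")
  odd <- make_region_volume(10, region = "NotInCatalog")
  expect_warning(regionalVolumes(odd, array(1, dim = dim(odd@grid))),
                 "not in catalog")
})

test_that("ICV normalization is the plain ratio and guarded", {
  coh <- make_two_group_cohort(n_patient = 4, n_control = 4, seed = 2)
  nm <- normalizeByIcv(coh)
  icv_mm3 <- subjectData(coh)$icv_cm3 * 1000
  expect_equal(volumes(nm), sweep(volumes(coh), 2, icv_mm3, "/"))
  expect_true(isNormalized(nm))
  # worked ratio: 3000 mm^3 over 1,500,000 mm^3 ICV
  v <- volumes(coh); v["Hippocampus_L", 1] <- 3000
  cd <- as.data.frame(subjectData(coh)); cd$icv_cm3[1] <- 1500
  coh2 <- TleCohort(v, cd)
  expect_equal(volumes(normalizeByIcv(coh2))["Hippocampus_L", 1], 0.002)
  # scaling a subject's ICV and volumes together is a no-op after normalizing
  v3 <- v; v3[, 1] <- v3[, 1] * 2
  cd3 <- cd; cd3$icv_cm3[1] <- cd3$icv_cm3[1] * 2
  expect_equal(volumes(normalizeByIcv(TleCohort(v3, cd3)))[, 1],
               volumes(normalizeByIcv(coh2))[, 1])
  # normalization preserves within-subject ratios exactly
  r_raw <- volumes(coh)[, 2] / volumes(coh)["Hippocampus_L", 2]
  r_nrm <- volumes(nm)[, 2] / volumes(nm)["Hippocampus_L", 2]
  expect_equal(r_raw, r_nrm)
  expect_error(normalizeByIcv(nm), "already")
})

test_that("cohort tables round-trip through delimited text", {
  coh <- make_two_group_cohort(n_patient = 5, n_control = 4, seed = 8)
  path <- tempfile(fileext = ".csv")
  writeCohort(coh, path)
  back <- readCohort(path)
  expect_equal(volumes(back), volumes(coh), tolerance = 1e-9)
  expect_identical(colnames(back), colnames(coh))
  expect_false(isNormalized(back))
  # normalized flag survives the round trip
  npath <- tempfile(fileext = ".csv")
  writeCohort(normalizeByIcv(coh), npath)
  expect_true(isNormalized(readCohort(npath)))
})

test_that("cohort reader errors name the offending columns", {
  coh <- make_two_group_cohort(n_patient = 3, n_control = 3, seed = 9)
  path <- tempfile(fileext = ".csv")
  writeCohort(coh, path)
  df <- utils::read.csv(path, check.names = FALSE)
  df$Amygdala_R <- NULL
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(df, bad, row.names = FALSE)
  expect_error(readCohort(bad), "Amygdala_R")
  # duplicate ids
  df2 <- utils::read.csv(path, check.names = FALSE)
  df2$subject_id[2] <- df2$subject_id[1]
  dup <- tempfile(fileext = ".csv")
  utils::write.csv(df2, dup, row.names = FALSE)
  expect_error(readCohort(dup), "duplicate")
})

test_that("unknown extra columns ride along as metadata, not structures", {
  coh <- make_two_group_cohort(n_patient = 3, n_control = 3, seed = 10)
  path <- tempfile(fileext = ".csv")
  df <- utils::read.csv(writeCohort(coh, path), check.names = FALSE)
  df$scanner_site <- "site_A"
  utils::write.csv(df, path, row.names = FALSE)
  back <- readCohort(path)
  expect_true("scanner_site" %in% colnames(subjectData(back)))
  expect_equal(nrow(back), 83)
})

test_that("label volumes round-trip through NIfTI", {
  lv <- generateLabelPair(c(6, 5, 4), 3, 0.2, seed = 4)$degraded
  path <- tempfile(fileext = ".nii.gz")
  writeLabelVolume(lv, path)
  back <- readLabelVolume(path, codes = lv@codes)
  expect_equal(back@grid, lv@grid)
  expect_equal(back@voxelDims, lv@voxelDims, tolerance = 1e-6)
})
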