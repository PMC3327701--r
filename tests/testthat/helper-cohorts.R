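# Fixtures built in code: small cohorts and label images for the tests.

# Two-group cohort: controls vs a patient-like group with given planted
# effects (named numeric of fractional reductions).
make_two_group_cohort <- function(n_patient = 30, n_control = 28,
                                  effects = c(Hippocampus_L = 0.30),
                                  noise_cv = 0.08, seed = 1,
                                  patient_name = "TLE-HA_L",
                                  icv_patient = 1387, icv_control = 1483) {
  cfg <- cohortConfig(list(
    groupSpec("control", n_control, icv_control, 160),
    groupSpec(patient_name, n_patient, icv_patient, 128, effects = effects)),
    noise_cv = noise_cv, seed = seed)
  generateCohort(cfg)
}

# Null cohort: two groups drawn from the identical generative process.
make_null_cohort <- function(n_a = 15, n_b = 15, seed = 1, noise_cv = 0.08) {
  cfg <- cohortConfig(list(
    groupSpec("TLE-N_L", n_a, 1450, 150),
    groupSpec("TLE-N_R", n_b, 1450, 150)),
    noise_cv = noise_cv, seed = seed)
  generateCohort(cfg)
}

two_class_labels <- function(cohort) {
  droplevels(factor(subjectData(cohort)$group))
}

# Tiny label volume with one coded region of `n_vox` voxels labelled 1.
make_region_volume <- function(n_vox = 10, shape = c(5, 5, 5),
                               region = "Hippocampus_L",
                               voxel_dims = c(1, 1, 1)) {
  g <- array(0L, dim = shape)
  g[seq_len(n_vox)] <- 1L
  LabelVolume(g, voxelDims = voxel_dims, codes = c("1" = region))
}

# Small classifier specs that keep grid search light in unit tests.
fast_vol_spec <- function(...)
  classifierSpec("volumetric", C_grid = c(1, 64),
                 gamma_grid = c(2^-5, 2^-1), D_grid = c(1, 3), ...)
fast_spec_spec <- function(...)
  classifierSpec("spectral", C_grid = c(1, 64), D_grid = c(1, 3), ...)
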