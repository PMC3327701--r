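# tleMorph

Whole-brain morphometric classification and lateralization of temporal
lobe epilepsy (TLE) from regional brain volumes.

In unilateral TLE, volume loss is not confined to the hippocampus: the
amygdala, parahippocampal gyrus, thalamus, orbitofrontal cortex and other
structures shrink ipsilaterally to the seizure focus — sometimes so subtly
that expert readers call the scan normal (MRI-negative TLE, "TLE-N", as
opposed to TLE with visible hippocampal atrophy, "TLE-HA"). This package
implements the full analysis chain for detecting and lateralizing that
signature from an 83-structure volume table, for neuroimaging researchers
who want a tested, seedable, leak-checked reference implementation:

* **Volumetry** — grey-matter-masked regional volumes from label + GM
  probability images (strict 50% threshold, 18 unmasked full structures),
  intracranial-volume (ICV) ratio normalization, cohort table I/O.
* **Label fusion** — per-voxel vote-rule fusion of multi-atlas candidate
  segmentations; Dice/Jaccard overlap evaluation.
* **Structure selection** — a kernel-based two-class separability
  criterion, J = ‖μ₁ − μ₂‖²_H / (s₁ + s₂ + ε), applied per structure
  (Best Individual N). Under the linear kernel J reduces exactly to the
  Fisher ratio, which the tests use as an independent oracle.
* **Spectral features** — per structure, subjects are embedded with the
  k = 2 smallest eigenvectors of the Laplacian of the Gaussian similarity
  graph W_ij = exp(−(z_i − z_j)²/c), c = 2, on z-scored volumes; blocks
  concatenate into an N × kD feature matrix.
* **Classification** — RBF-SVM on selected volumes and linear SVM on
  spectral features (libsvm via e1071), nested leave-one-out grid search
  over (C, γ, D), repeated stratified k-fold evaluation, side-specific
  classifier combination by maximum Platt posterior, and permutation
  testing with structure selection re-run inside every permutation.
* **Synthetic cohorts** — a generator emulating the study's group
  structure (28 controls, 60 TLE-HA, 20 TLE-N with left/right focus
  splits), volume ∝ ICV with lognormal noise and graded, lateralized,
  mirrored atrophy effects, so the whole pipeline is testable without
  any scan data.

See `vignette("tle-morphometry")` for the methods account and the design
decisions.

## Worked example

Classify synthetic TLE-HA (left focus) patients against controls:

```r
library(tleMorph)

coh  <- generateCohort(defaultCohortConfig(seed = 7))
norm <- normalizeByIcv(coh)
g    <- subjectData(norm)$group
sub  <- norm[, g %in% c("TLE-HA_L", "control")]
lab  <- droplevels(factor(subjectData(sub)$group))

rk <- rankStructuresBin(sub, lab, D = 6)
rk
#> StructureRanking: 83 structures, top D = 6
#>    1. Hippocampus_L        J = 4.3
#>    2. Amygdala_L           J = 1.076
#>    3. FusiformG_L          J = 0.7215
#>    4. AntTempLobeLat_L     J = 0.5809
#>    5. AntOrbitalG_L        J = 0.409

spec <- classifierSpec("volumetric", C_grid = c(1, 64),
                       gamma_grid = c(2^-5, 2^-1), D_grid = c(1, 3))
evaluateRepeatedKfold(sub, lab, spec, folds = 10, repeats = 10, seed = 7)
#> cvReport (volumetric scheme): 10-fold CV x 10 repeats
#>   accuracy    97.9 +/- 0.8 %
#>   sensitivity 99.7 +/- 1.0 %
#>   specificity 95.7 +/- 1.5 %

permutationTest(sub, lab,
                classifierSpec("volumetric", C_grid = 1,
                               gamma_grid = 2^-3, D_grid = 3),
                n_permutations = 500, seed = 7)
#> PermutationResult: observed 100.0%, null 66.0 +/- 6.4% (500 perms)
#>   p = 0.001996, standardized statistic = 5.340
```

The ranking recovers the planted atrophy gradient (hippocampus first, then
amygdala and temporal structures); cross-validated accuracy of ~98% means
nearly every subject is assigned to the correct group across 10×10 folds;
the permutation p of 0.002 says no label shuffle among 500 — each with
selection re-run — reached the observed accuracy. Note the null mean of
66%, not 50%: re-selecting structures inside each permutation absorbs the
optimistic bias that selection would otherwise inject, which is exactly
why it must be inside.

The five standard experiments (TLE-HA vs control, TLE-HA lateralization,
TLE-HA vs TLE-N, TLE-N vs control, TLE-N lateralization) are one call
each:

```r
report <- runExperiment(experimentConfig("exp2", seed = 4))
writeExperimentReport(report, "report_exp2")
```

or from a shell: `Rscript inst/scripts/run_experiment.R --experiment exp2
--seed 4 --out report_exp2`.

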