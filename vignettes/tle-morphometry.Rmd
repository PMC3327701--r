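---
title: "Morphometric classification and lateralization of temporal lobe epilepsy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric classification and lateralization of temporal lobe epilepsy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tleMorph)
```

## The problem

Unilateral temporal lobe epilepsy (TLE) leaves a morphometric signature on
the brain: in patients with hippocampal atrophy (TLE-HA) the ipsilateral
hippocampus is visibly smaller, and volume loss extends to the amygdala,
parahippocampal gyrus, thalamus and other structures. In a substantial
minority of patients the MRI looks normal to expert readers (TLE-N), yet
subtle, spatially distributed volume differences remain. This package
implements a whole-brain volumetric pipeline that (i) ranks 83 brain
structures by how well their volumes separate two diagnostic groups,
(ii) classifies subjects with support-vector machines under two feature
schemes, and (iii) assesses significance by label permutation — together
with a synthetic cohort generator so that every stage is testable without
patient scans.

## Regional volumetry

Volumes are defined over a fixed 83-structure catalog (40 bilateral pairs
plus brainstem, corpus callosum and third ventricle; see
`structureCatalog()`). Given an integer label image and a grey-matter (GM)
probability map on the same grid, `regionalVolumes()` counts, for cortical
structures, only voxels whose GM probability strictly exceeds 0.5 — a voxel
at exactly 50% is excluded. Eighteen structures are exempt from this
masking and counted as full structures: the ventricular CSF spaces and
corpus callosum (which contain no grey matter to mask) and the subcortical
grey nuclei — caudate, accumbens, pallidum, putamen, substantia nigra,
thalamus, brainstem — whose GM probability is typically misclassified at or
below 50% by tissue segmentation. A literal bilateral expansion of that
prose list gives 19 regions against the fixed count of 18 full structures;
the shipped catalog resolves this by keeping the third ventricle in the
masked set, where its GM-masked volume is essentially zero and it never
contributes to discrimination. The catalog JSON records this choice.

Head size is a confound, so analysis operates on dimensionless ratios:
`normalizeByIcv()` divides each volume (mm³) by the subject's intracranial
volume (ICV, converted from cm³). The plain ratio is used — no residual
regression — and a flag on the cohort object guards against normalizing
twice.

Multi-atlas pipelines produce one candidate segmentation per atlas;
`voteFuse()` combines them by per-voxel majority. Ties are broken toward
the lowest label code, which makes fusion deterministic and independent of
candidate order. Overlap evaluation uses the Dice coefficient
2|A∩B|/(|A|+|B|) by default (Jaccard is available), with the convention
that two empty regions overlap perfectly.

## Structure selection

For each structure independently, the volumes are z-scored and a
kernel-based two-class separability criterion is computed: with kernel
$k$ and classes $c_1, c_2$,

$$J = \frac{\lVert \mu_1 - \mu_2 \rVert_H^2}{s_1 + s_2 + \varepsilon},$$

where $\mu_c$ is the class mean in the kernel-induced feature space,
$s_c = \mathbb{E}[k(x,x)] - \mathbb{E}_{x,x' \in c}[k(x,x')]$ is the
within-class scatter, and $\varepsilon$ (default $10^{-8}$) guards the
denominator. The criterion makes no assumption about the class-conditional
densities and remains informative for small classes. Under the linear
kernel it reduces exactly to the Fisher-style ratio (squared difference of
class means over summed within-class population variances) — the package's
test suite exploits this as an independent oracle. The default kernel is
Gaussian, $k(x,y) = \exp(-(x-y)^2 / 2\sigma^2)$, with $\sigma$ set by the
median heuristic (median pairwise absolute difference of the z-scores,
floored at $10^{-3}$), which makes $J$ invariant under affine rescaling of
the feature.

Selection is Best Individual N (BIN): the criterion is applied to each of
the 83 structures on its own and the top $D$ are kept. Ranking ties are
broken by canonical catalog order, and a zero-variance structure scores
$J = 0$. BIN is deliberately univariate; no wrapper or multivariate
selection is attempted.

## Spectral features

The second feature scheme converts pairwise subject similarity into
per-subject features. Per selected structure: volumes are z-scored with the
population (divisor-$N$) convention, the complete similarity graph
$W_{ij} = \exp(-(z_i - z_j)^2 / c)$ with $c = 2$ is formed, its Laplacian
taken, and the eigenvectors of the $k = 2$ smallest eigenvalues used as
features; blocks from the $D$ structures are concatenated into an
$N \times kD$ matrix.

Three choices here were genuinely open and are fixed as follows:

* **Laplacian variant** — unnormalized $L = \mathrm{Deg} - W$ by default.
  On a fully connected positive graph every variant is well defined; the
  unnormalized form keeps the constant vector as the exact 0-eigenvector,
  which makes the algebra directly testable (row sums zero, PSD, Fiedler
  sign pattern). The symmetric normalized form is available.
* **Eigenvector sign** — an eigenvector is only defined up to sign, so each
  column is flipped to make its largest-magnitude entry (first such entry
  on ties) positive. Features are therefore byte-reproducible.
* **The trivial eigenvector** — with $k = 2$ the first (near-constant)
  eigenvector is retained rather than skipped, since the construction asks
  for the eigenvectors of the $k$ smallest eigenvalues with no skip rule;
  `skip_trivial = TRUE` switches to eigenvectors 2 and 3.

The embedding is transductive by default: the graph is built over all
subjects in the experiment, train and test together. This mirrors the
per-cohort construction of the Laplacians but leaks the test subjects'
*feature values* (never their labels) into training. The evaluation module
therefore also offers `embed = "nystrom"`, which builds graphs on the
training split only and places test subjects by the out-of-sample extension
$u_{\text{new}} = \langle w, u \rangle / (d - \lambda)$ derived from the
eigenpair equation. Both modes are exercised in the tests; accuracy
differences on strongly separated synthetic cohorts are small.

## Classification and evaluation

The volumetric scheme applies an RBF-SVM to the selected ICV-normalized
volumes; the spectral scheme applies a linear SVM to the spectral features
(both via libsvm). Hyperparameters come from an exhaustive grid over the
slack penalty $C$, RBF width $\gamma$ and the number of structures $D$,
scored by leave-one-out accuracy on the training split only; ties break
toward smaller $D$, then $C$, then $\gamma$. The wide libsvm-guide default
grids ($C = 2^{-5} \ldots 2^{15}$, $\gamma = 2^{-15} \ldots 2^{3}$, powers
of four; $D = 1 \ldots 20$) are appropriate for a one-off analysis; the
experiment configurations default to small grids that keep desk-scale runs
fast, because on strongly separated synthetic cohorts the optimum is flat.

Evaluation is repeated stratified k-fold cross-validation (10 folds × 10
repeats by default; 5 folds for 20-subject experiments). Structure ranking
runs inside each training split — the inner grid search reuses that
split-level ranking rather than re-ranking per inner leave-one-out fold —
and the held-out fold is never touched until prediction. This is not left
to discipline: `evaluateRepeatedKfold()` logs, for every fold, the exact
subject indices and labels the ranking saw, and the test suite asserts the
log excludes every held-out index. Patients (left-focus, in lateralization
tasks) are the positive class for sensitivity. For screening-style designs
with left- and right-focus patients, side-specific classifiers can be
trained and combined: a subject is a patient when the larger of the two
Platt posteriors strictly exceeds 0.5.

Significance uses permutation: labels are shuffled, structure ranking is
re-run on the shuffled labels (selection inside the permutation — omitting
this step inflates significance), and a full leave-one-out
cross-validation of a classifier on the top-ranked structures is scored;
$p = (1 + \#\{\text{null} \ge \text{observed}\})/(1 + n_{\text{perm}})$,
with the observed accuracy computed by the identical procedure on the
unpermuted labels. Inside permutations the hyperparameters are fixed at the
first grid values — re-running the full grid search 10,000 times buys
little and costs much. The standardized statistic
$(\text{obs} - \bar{a}_{\text{null}})/s_{\text{null}}$ is reported
alongside; the $p$-value is the contract. Because leave-one-out accuracy is
discrete, null draws tie with the observed value and the $p$-value is
conservative (its null distribution sits above uniform); the test suite
bounds this departure with a DKW band over 50 replicate null cohorts, using
40 subjects and a two-structure classifier so the accuracy statistic has
enough distinct levels for the check to be informative.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, not
images. Per subject, ICV is drawn from the group's normal distribution
(truncated positive); per structure,

$$v_s = f_s \cdot \mathrm{ICV} \cdot (1 - e_s) \cdot e^{\epsilon}, \qquad
\epsilon \sim N(0, \sigma^2),\ \sigma^2 = \log(1 + \mathrm{cv}^2),$$

with $f_s$ the structure's base ICV fraction, $e_s$ the group's fractional
atrophy effect and cv the multiplicative noise coefficient of variation
(default 0.08, a typical regional-volume CV). Proportionality to ICV
reproduces the positive hippocampus–ICV correlation expected in every
subgroup; lognormal noise keeps volumes positive.

The default study-sized configuration has five groups: 28 controls
(ICV 1483 ± 160 cm³), 60 TLE-HA split 33 left / 27 right (1387 ± 128), and
20 TLE-N split 11 left / 9 right (1423 ± 150). Atrophy effects are defined
ipsilaterally and mirrored to the other side by a structure-name side-swap:
TLE-HA plants a 0.30 hippocampal reduction with eight further structures
graded 0.15 → 0.05 (amygdala, anterior orbital gyrus, lateral anterior
temporal lobe, fusiform gyrus, thalamus, cerebellum, parahippocampal gyrus,
medial orbital gyrus); TLE-N plants a subtler 0.10 → 0.03 gradient over ten
orbitofronto-temporal and nigral structures, led by the substantia nigra.
The gradients make the single-structure separability ordering match the
intended phenotypes. Absolute per-structure reference volumes are
order-of-magnitude adult values stored in the catalog (synthetic, not
measured from any cohort); only their ratios to ICV matter downstream. Age
and sex are generated for the demographics block but carry no volume
effect, consistent with the absence of a sex effect on ICV-adjusted
volumes in this setting.

What the generator does **not** emulate: segmentation error and its spatial
correlation, scanner and field-strength bias, age-related atrophy,
correlated noise across structures, and non-lognormal outliers. Passing
tests on synthetic cohorts therefore demonstrate that the machinery is
correct and leak-free under the stated generative assumptions — not that
the printed accuracies of any real cohort are reproduced. Label-image
fixtures for the fusion module are slab partitions with a controlled
fraction of voxels reassigned to a random other label, which gives exact
expected overlaps (a fully flipped volume has zero region overlap with the
original).

## Numerical and degenerate-input conventions

* Strict GM threshold (> 0.5); ties excluded.
* Ranking: z-scored features; zero-variance feature ⇒ $J = 0$; ranking ties
  ⇒ catalog order; $\varepsilon = 10^{-8}$ in the criterion denominator.
* Spectral: divisor-$N$ z-scores; zero-variance structure is an error
  naming the structure; eigensign convention as above; Nystrom denominators
  guarded at $10^{-8}$.
* Folds: stratified; degenerate draws (a training split losing a class)
  are redrawn up to 100 times, then error; `folds = n` is exact
  leave-one-out.
* Vote fusion ties ⇒ lowest label code; Dice of two empty sets ⇒ 1.
* All randomness flows through explicit seeds (`withr::with_seed`), so
  cohorts, fold assignments and reports regenerate identically.

## Problem sizes in the test suite

The shipped tests run the full pipeline at the study's group sizes
(28/60/20), 100-seed calibration and recovery sweeps, 10 × 10-fold CV for
the planted-effect checks, and 50 × 200 permutations for the null
uniformity check — sizes chosen to give each statistical assertion a
comfortable margin while keeping a complete run to a few minutes on one
core. The wide default grids and 10,000-permutation significance runs
remain available for real analyses.

## Limitations

* The criterion's exact kernel parameterization in the original line of
  work is not published in the text available here; the implemented RKHS
  between/within form is fixed by this package and validated against its
  linear-kernel reduction.
* Transductive spectral features leak test feature values by construction;
  use `embed = "nystrom"` for honest generalization estimates.
* The permutation $p$-value is conservative under heavy accuracy ties
  (small cohorts, single-structure classifiers).
* Binary classification only; multi-class designs (type × lateralization)
  are out of scope.
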