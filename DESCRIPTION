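Package: tleMorph
Title: Whole-Brain Morphometric Classification and Lateralization of Temporal Lobe Epilepsy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for classifying temporal lobe epilepsy patients
    and lateralizing the presumed seizure focus from regional brain volumes.
    Provides vote-rule fusion of multi-atlas label volumes, grey-matter-masked
    regional volumetry over an 83-structure catalog with intracranial-volume
    normalization, kernel-based class-separability structure ranking (Best
    Individual N), graph-Laplacian spectral embedding of pairwise subject
    similarities, RBF and linear support-vector classification with nested
    grid search, repeated stratified cross-validation, permutation testing of
    classifier accuracy, and a synthetic cohort generator that emulates the
    group structure of a controls / TLE with hippocampal atrophy / MRI-negative
    TLE study so the whole pipeline is testable without patient scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    jsonlite,
    RNifti,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
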