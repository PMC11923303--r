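Package: PatchTIL
Title: Patch-Level Tumor-Infiltrating Lymphocyte Scoring for H&E Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring tumor-infiltrating lymphocytes (TILs) in
    hematoxylin-and-eosin stained slide images at patch level: non-overlapping
    150x150 tiling with a blank-tissue filter, Macenko stain normalization,
    a pluggable three-class patch classifier (TIL-positive / TIL-negative /
    other-necrotic) with a rule-based nucleus-detection reference backend,
    pooled TIL scores per slide and per patient, cohort kernel-density
    summaries, and patch-level TIL maps. Includes a seeded synthetic H&E
    patch and slide generator with ground-truth cell counts so the whole
    pipeline is testable without whole-slide images, plus multi-class
    evaluation (confusion matrix, accuracy, Cohen's kappa, one-vs-rest AUC,
    precision, recall, specificity, F1) and stratified split and
    cross-validation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    pROC,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    caret
Config/testthat/edition: 3
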