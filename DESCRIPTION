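Package: pmapdose
Title: Voxel-Region-Aware Dosimetric Analysis for Lung Radiotherapy Plans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing thoracic radiotherapy dose distributions
    around a pneumonitis-associated lung sub-region (Pmap). Provides a
    shared voxel-lattice data model for dose grids and binary structure
    masks, linear-quadratic biologically effective dose (BED) conversion,
    dose-volume histogram (DVH) metric panels, plan conformity and
    heterogeneity indices, Dice overlap, transfer of a phantom-defined
    sub-region into patient space, threshold-based acute pulmonary
    toxicity (APT) risk classification with a pluggable logistic
    surrogate model, cohort assignment and optimization-success
    adjudication for paired initial/optimized plans, reclassification
    summaries, and ROC/Youden cutoff analysis. A synthetic thoracic
    phantom and plan-pair painter make the whole pipeline testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
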