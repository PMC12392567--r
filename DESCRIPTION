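Package: npxpanel
Title: Biomarker Panel Discovery and Validation for Targeted CSF Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovery and validation of
    cerebrospinal-fluid protein biomarker panels from targeted
    proximity-extension-assay (PEA) data reported in NPX (log2) units.
    Covers limit-of-detection filtering, bridging-sample batch
    harmonization across measurement rounds, per-protein differential
    abundance via nested linear models with age and sex adjustment and
    Benjamini-Hochberg FDR control, cross-contrast overlap
    categorization, hypergeometric term enrichment, elastic-net
    penalized logistic panel selection over a mixing-parameter and
    marker-cap grid with balanced cross-validation and fold-based
    stability selection, ridge refitting of final signatures, repeated
    cross-validated AUC with percentile confidence intervals, external
    cohort validation of frozen panels, Passing-Bablok method-comparison
    regression for cross-platform assay conversion, and
    covariate-adjusted partial Spearman correlations with clinical
    scores. Includes a synthetic cohort generator with planted effects
    for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
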