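Package: hdacscreen
Title: Shrunken-Centroid Transcriptomic Biomarker Screening for HDAC
    Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Derives and applies nearest-shrunken-centroid (NSC)
    transcriptomic biomarkers that separate histone deacetylase inhibitor
    (HDACi) exposures from other modes of action in control-normalized
    expression profiles. Provides the full workflow from raw targeted
    RNA-seq counts (counts-per-million normalization, vehicle-control
    ratios, replicate averaging, correlation-based quality control and
    outlier removal) through NSC training with soft-threshold centroid
    shrinkage and compound-level cross-validation, probability-based
    classification at a 90 percent posterior cutoff, and corroborating
    principal-component and hierarchical-clustering calls. Ships a frozen
    19-gene HDACi biomarker panel as a built-in classifier and a synthetic
    data generator matching the classifier's statistical assumptions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
biocViews: Classification, GeneExpression, Transcriptomics, QualityControl
RoxygenNote: 7.3.3
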