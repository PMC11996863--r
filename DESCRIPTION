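Package: phosflow
Title: Differential Phosphoproteomics of Paired Insulin-Stimulation Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for phosphosite-level analysis of paired
    basal/insulin-stimulation phosphoproteomics experiments comparing control
    and type 2 diabetes donors. Provides localization-probability filtering,
    truncated-normal KNN imputation of intensity-dependent missingness, median
    normalization, surrogate-variable batch adjustment, empirical-Bayes
    moderated t and F statistics on paired designs, a six-way taxonomy of
    impaired and emergent insulin-signaling phosphosites, hierarchical
    clustering with variable-height dendrogram cutting, hypergeometric
    over-representation analysis, and kinase substrate-motif enrichment
    (position-specific scoring matrix percentiles, Haldane-corrected frequency
    factors, one-sided Fisher tests). A synthetic-data generator with planted
    ground truth emulates the study design so every stage is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    limma,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
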