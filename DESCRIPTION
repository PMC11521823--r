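Package: pairomics
Title: Paired Pre/Post Multi-Omics Biomarker Discovery and Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for paired before/after intervention studies that
    profile histone post-translational modifications (buccal cells, PBMCs) and
    the plasma proteome. Covers feature filtering, quantile normalization,
    left-censored (NMAR) and random (MAR) missing-value imputation,
    empirical-Bayes batch adjustment, precursor-group relative abundances,
    composite marker discovery (paired tests intersected with jackknifed PLS-DA
    VIP bounds), similarity network fusion with spectral clustering,
    cross-omics change-correlation networks, effect-size trend classification
    over ordinal response categories, and lifestyle-based health-awareness
    scoring. Ships a synthetic-cohort generator with ground truth so every
    stage is testable without access to the original measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    mclust,
    sva,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
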