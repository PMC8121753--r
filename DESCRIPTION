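Package: groatlab
Title: Oat Grain Metabolomics and Nitrogen-Response Agronomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing nitrogen-response field trials of winter oats
    at the grain-composition level. Covers quality filtering and normalisation
    of deconvolved LC-MS/GC-MS feature tables (retention-window and blank
    exclusion, pooled-QA relative-standard-deviation filtering, TIC and
    internal-standard normalisation), correlation-based grouping of co-eluting
    features with adduct/isotope annotation and neutral-mass library matching
    at ppm tolerance, GC-MS retention-index plus spectral-similarity
    identification, multiblock hierarchical (consensus) PCA under variety or
    nitrogen blocking, non-parametric nitrogen screening (Spearman rho,
    Friedman tests with Benjamini-Hochberg FDR), Spearman-distance
    clustergrams and heatmap matrices, and the agronomic computations:
    lodging index, yield components from grain yield and thousand-grain
    weight, split-plot ANOVA with Fisher's protected LSD letters, and the
    linear-plus-exponential nitrogen dose-response model with its economic
    optimum. A synthetic-data module generates feature tables and field-trial
    plot data with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
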