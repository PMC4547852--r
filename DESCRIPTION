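Package: oncoepi
Title: Epistatic Interaction Detection in Cancer Alteration Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects co-occurrence and mutual-exclusivity (epistatic)
    interactions between binary somatic driver alterations across tumor
    cohorts using a fixed-margin checkerboard-swap permutation null that
    preserves per-sample alteration load and per-alteration recurrence
    within each cancer-type by alteration-class block. Provides empirical
    P-values with Benjamini-Hochberg FDR control, per-cancer-type and
    pan-cancer screens, Breslow-Day/Tarone tests for differential
    interactions between cancer types calibrated by the same permutation
    null, protein-protein-interaction enrichment by resampling, saturation
    (down-sampling) curves, Mann-Whitney ranking of candidate driver genes
    inside copy-number regions, and a synthetic-cohort generator with
    planted interactions of known odds ratio for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    metafor,
    vegan,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
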