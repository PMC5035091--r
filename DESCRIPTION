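Package: hetevo
Title: Evolution of Gene Expression and Its Plasticity Under Heterogeneous Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for experimental-evolution transcriptomics in
    which replicate populations evolve under constant or heterogeneous
    (temporally or spatially varying) selective regimes and are assayed in two
    environments. Implements countergradient divergence analysis (ancestral
    plasticity versus evolved divergence, polarized per-block pair
    divergence), ancestor-based screens for genes predicted to evolve
    increased or decreased plasticity, the adaptive-distance metric Phi,
    regime-level comparisons (ANOVA/Tukey HSD and a nested
    heterogeneity-class likelihood-ratio test), and an allelic-plasticity
    scan from pooled RNA-seq allele counts (site screening,
    Cochran-Mantel-Haenszel tests stratified by replicate population, a
    permutation-enrichment null for the association between allelic and
    abundance plasticity, and a direction-alignment bootstrap against genomic
    SNP differentiation). A synthetic-data generator reproduces the study
    design (4 regimes x 5 replicate populations x 2 assay diets in 5 blocks
    plus 3 ancestors in a 6th block) with planted gene classes so every stage
    can be validated against ground truth.
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
    withr,
    yaml
Config/testthat/edition: 3
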