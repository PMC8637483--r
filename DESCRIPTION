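Package: contamscope
Title: Negative-Control-Aware Analysis of Low-Biomass Amplicon Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing 16S amplicon sequence variant (ASV) count
    tables from low-microbial-biomass specimens, such as individual insect
    guts, where reagent contamination and cross-contamination dominate a
    large share of reads. Implements a major-contaminant classifier that
    flags ASVs both prevalent across specimens and enriched in extraction
    negative controls, a prevalence-rule reference classifier, a
    specimen-to-matched-control Bray-Curtis proximity screen, alpha and beta
    diversity with negative controls retained in every output, PERMANOVA
    with seeded permutations and factor interactions, a simplified
    negative-binomial Wald test for genus-level differential abundance, a
    Gehan-Breslow-Wilcoxon survival comparison, and a synthetic study
    generator with biomass-dependent contamination and known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    survival,
    biomformat,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
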