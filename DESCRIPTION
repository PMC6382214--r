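Package: mireqtl
Title: Population-Aware miRNA/Host-Gene eQTL Analysis and Paradox Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cis-eQTL analysis of microRNAs and their host genes in
    multi-population cohorts. Implements the full association panel (simple
    linear regression, one-way ANOVA, type II ANCOVA, random-intercept linear
    mixed models, Welch t-tests, plain and population-adjusted Pearson
    correlations), detectors for Simpson-like masking, non-transitive
    correlation and miRNA/host-gene uncoupling, a genome-wide stem-loop SNP
    scan with strand-aware position annotation, quantification of qPCR
    (delta-Ct, delta-delta-Ct) and dual-luciferase reporter data, and
    screening filters for candidate miRNA target genes. Includes exact-mode
    simulators that reconstruct the Simpson-paradox and non-transitivity
    example datasets and a Hardy-Weinberg multi-population cohort simulator
    with zero-inflated miRNA counts, so every stage can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    lme4,
    jsonlite,
    vcfR,
    rtracklayer,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
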