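Package: hydroxycall
Title: Single-Base 5hmC Calling and Cross-Platform Hydroxymethylation
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies 5-hydroxymethylcytosine (5hmC) from paired
    bisulphite (Bis) and oxidative bisulphite (OxBis) experiments by
    binomial subtraction at single-CpG resolution, with coverage
    filtering, two-proportion significance testing and the region-level
    discard/impute averaging rules used in cross-platform 5hmC studies.
    Also provides array-style differential calling on logit-transformed
    beta values with empirical-Bayes variance moderation, genomic-feature
    enrichment with hypergeometric testing, hMeDIP-seq tile enrichment
    with a fixed-dispersion negative-binomial exact test and a
    length-preserving permutation null for specificity auditing, spike-in
    conversion/oxidation/protection efficiency estimators, and
    single-molecule amplicon pattern classification. A synthetic-data
    generator emulates the chemistry's error model (non-conversion,
    over-conversion, oxidation, TET and beta-glucosyltransferase
    efficiencies) and supplies ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    IRanges,
    S4Vectors
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
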