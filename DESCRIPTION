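Package: nightcontrast
Title: Dark-Period Transcriptome and Metabolome Contrasts Between Two
    Inbred Plant Accessions
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Comparative analysis of two homozygous plant accessions
    profiled during the dark period: single-nucleotide polymorphism
    calling from paired transcriptome pileups with a five-rule filter
    cascade, cluster filtering and a 999-capped quality tier;
    replicate-free negative-binomial differential-expression testing with
    median-of-ratios normalization and presence-absence classification;
    qRT-PCR primer-efficiency fitting and efficiency-corrected delta-CT
    quantification; mid-parent and transgressive heterosis statistics for
    F1 metabolite profiles (t tests, Tukey HSD, additive two-factor
    ANOVA, exact binomial and contingency tests, a starch-degradation
    proxy); and category-level Wilcoxon signed-rank enrichment of fold
    changes.  A synthetic-data generator with planted ground truth makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
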