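Package: dimorph
Title: Sex-Specific Brain Gene Regulation Analysis After Perinatal
    Low-Protein Diet
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable implementation of the analysis pipeline used
    to link perinatal low-protein diet to sex-specific gene regulation in the
    rodent brain: a replication-validated dual-model microarray differential
    expression screen with empirical-Bayes variance moderation and B-statistic
    ranking, an m-of-n consensus peak definition over replicate ChIP-seq peak
    calls with input-control exclusion, repeated-measures mixed models for
    bisulfite pyrosequencing CpG methylation, delta-Ct qPCR fold-change
    analysis against dual housekeeping genes, and a shared factorial
    GLM/estimated-marginal-means engine with Newman-Keuls and Bonferroni
    post-hoc procedures. A synthetic-data module emulates the study designs
    (factorial pooled microarrays with a dominant technical component,
    replicate peak sets, per-CpG methylation tables, Ct tables, behavioral
    measures) so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    lme4,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    car,
    knitr,
    rmarkdown
Config/testthat/edition: 3
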