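Package: ampbuffer
Title: Mutation Buffering by Somatic Copy-Number Amplifications in Tumor Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies whether somatic copy-number amplifications buffer the
    accumulation of deleterious coding mutations in cancer genomes. Implements
    a copy-neutral mutation rate (the mu score) that avoids the copy-number /
    mutation-count confounder, per-segment amplification and deletion
    frequencies at multiple genomic scales (genes, fixed-length bins,
    chromosome arms, whole chromosomes), rank-correlation analyses between
    amplification frequency and the mu score with gene- and mutation-property
    stratification, an additive oncogene / proliferation-gene / mu model of
    amplification patterns with a cohort-swap control, mutation-amplification
    relative timing from allele-specific copy number and mutation multiplicity,
    and a permutation-based per-gene protection index. A synthetic cohort
    generator with known ground truth (regional mutation-rate heterogeneity,
    CNA event-size mixture, allele-specific copy number with mutation
    multiplicities) provides a test bed for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
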