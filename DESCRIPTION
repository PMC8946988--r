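Package: bivalint
Title: Integrative Analysis of Factorial Transcriptomes and Promoter
    Chromatin States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the joint analysis of a two-factor (hormone
    stimulation by chromatin-remodeler knockdown) bulk RNA-seq experiment
    with promoter chromatin states derived from replicated ChIP-seq peak
    calls. Provides negative-binomial differential expression for the 2x2
    factorial design with covariate-weighted false discovery rate control,
    cooperative/antagonistic co-regulation classification, bivalent-promoter
    (H3K4me3 + H3K27me3) calling from replicate-consensus peaks, promoter
    binding and super-enhancer association with hypergeometric and Fisher
    enrichment statistics, gene-set enrichment with permutation-normalized
    scores, cross-sample promoter-mark versus expression testing, and a
    synthetic-data generator with planted ground truth for end-to-end
    validation of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    MASS,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    fgsea,
    jsonlite,
    knitr,
    optparse,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
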