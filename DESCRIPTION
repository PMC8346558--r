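Package: nr3cseq
Title: Integrated ChIP-Seq and RNA-Seq Analysis of Corticosteroid Receptor
    Genomic Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for the joint analysis of mineralocorticoid
    receptor (MR) and glucocorticoid receptor (GR) ChIP-seq together with
    intronic/exonic (hnRNA-aware) RNA-seq across baseline and acute-stress
    conditions. Provides window-based peak calling against input with local
    Poisson background, replicate-concordance classification of receptor
    selectivity, consensus peak sets, negative-binomial differential binding
    and expression with a constant/responsive taxonomy, position weight matrix
    scanning with exact p-values, binding-expression integration, and a
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    multcomp,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
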