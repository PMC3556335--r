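Package: DeNovoTriage
Title: Triage of De Novo Assembled Transcriptome Contigs Against a Reference Genome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-assembly inference for cultivar transcriptomics: filtering of
    called polymorphisms and projection of their coding consequences onto an
    annotated reference, alignment-gated triage of de novo assembled contigs
    (chimera and fragment exclusion, locus assignment, fraction-of-major-isoform
    pre-mRNA filtering, intron-chain isoform comparison, merged-gene detection),
    classification of novel loci and cultivar-private genes by open reading
    frames, coding potential and homology evidence, and negative-binomial
    expression profiling across berry development stages with four-pattern
    profile clustering and hypergeometric term enrichment. Includes a seeded
    synthetic-study generator with machine-readable planted truth for every
    downstream class.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    BiocGenerics,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    igraph
Suggests: testthat (>= 3.0.0), jsonlite, withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
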