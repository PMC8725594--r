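Package: methylcycle
Title: Bacterial Methylome Profiling and Cell-Cycle Modelling of CcrM Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide DNA methylation in rhizobia
    (genus Ensifer) and related Alphaproteobacteria. Scans degenerate (IUPAC)
    methyltransferase recognition motifs and computes their density in coding,
    intergenic and whole-genome partitions with a closed-form random-sequence
    expectation; profiles the extent of methylation along circular replicons in
    sliding windows with robust quadratic trend fits and frown/flat/smile
    pattern classification; models cell-cycle-gated CcrM (GANTC) methylation in
    asynchronous populations, including bacteroid differentiation regimes with
    endoreduplication and late methyltransferase shutoff, via a closed form
    validated by an agent-based simulator; recovers degenerate motifs from
    methylated-position catalogues; infers relative replicon copy number from
    windowed sequencing depth; and tests promoter motif enrichment. A synthetic
    data generator produces genomes of controlled GC content, strain fixtures
    carrying defined motif inventories, methylation-call tables from cell-state
    mixtures with binomial sampling noise, and Poisson depth profiles with
    specified replicon copy ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    IRanges,
    rtracklayer,
    MASS,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
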