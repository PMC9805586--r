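Package: grenrich
Title: Functional Enrichment on Genomic Regions with the GREAT Binomial Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Local implementation of the GREAT algorithm for functional
    enrichment on genomic regions. Builds per-gene regulatory domains
    (basal window around the transcription start site plus neighbour-bounded
    extension), merges them into per-term region sets, and tests input
    regions for enrichment with an exact binomial tail, including a
    generalized background-restricted binomial test and the classic
    hypergeometric background test. Ships readers and writers for BED, GMT,
    UCSC chrom.sizes, tab-delimited gene tables and minimal GTF, a seeded
    synthetic-fixture generator for end-to-end testing, region-gene
    association tables with signed distances to the TSS, and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
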