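Package: lnccat
Title: Building and Characterising Catalogs of Long Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for building composite long
    non-coding RNA (lncRNA) gene models from assembled transcript
    annotation, classifying them by position relative to protein-coding
    genes (antisense, antisense-upstream/-downstream, lincRNA),
    summarising expression, differential expression, cell-type
    specificity and repeat content, discovering short conserved
    "microdomains" by all-vs-all seed-and-extend local alignment with
    Karlin-Altschul E-values against length- and AT-matched random
    controls, mapping synteny between two genomes through UCSC chain
    liftover, and quantifying overlap with epigenomic peaks and
    TSS-centered coverage metaprofiles. A seeded synthetic-data
    generator emulates every input format so the whole pipeline is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
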