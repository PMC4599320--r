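Package: kmerTax
Title: Species-Level Classification of Marker-Gene Amplicons with a
    k-mer Inverted Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns partial marker-gene amplicon sequences (16S rRNA,
    cpn60) to species using a k-mer containment score computed over an
    inverted index, with per-level ambiguity detection and bootstrap
    confidence estimates. Includes tools to build species reference
    databases from FASTA plus a taxonomy mapping file (length filter,
    binomial-name filter, per-species deduplication, Clostridium cluster
    annotation), a degenerate-primer variable-region extractor, a
    cross-validation and mock-community evaluation harness, and a seeded
    synthetic-fixture generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
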