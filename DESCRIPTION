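Package: tirinv
Title: Insertion Sequence Inversions from Ectopic Recombination between
    Terminal Inverted Repeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and classifies inversions of bacterial insertion
    sequence (IS) elements caused by ectopic recombination between their
    terminal inverted repeats (TIRs). Provides a forward simulator of
    per-locus multi-strain alignments with ground truth (canonical
    insertion on a phylogeny, inversion by each predicted recombination
    outcome, precise excision, neutral point mutations), element anatomy
    annotation (de novo TIR detection with a mismatch catalogue,
    transposase ORF finding, target-site duplication detection, sigma-70
    -35/-10 promoter box scanning), a five-outcome mechanism classifier
    keyed on the diagnostic TIR asymmetry, weighted (Sankoff) parsimony
    reconstruction of insertion/inversion/deletion events on a strain
    phylogeny, and a pipeline orchestrator with TSV/JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    GenomicRanges,
    IRanges,
    optparse,
    phangorn,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
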