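Package: carscan
Title: Operator Discovery and Binding Analysis for B12-Dependent
    Photoregulation of Carotenogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the coenzyme-B12 (AdoCbl)-based CarH
    photoreceptor/repressor family and its B12-independent paralogue CarA
    in myxobacteria. Classifies protein sequences as CarH or CarA
    homologues from co-occurrence of the Wx9EH, cobalamin-binding and
    RxWERRY motifs; discovers candidate operators as runs of tandem 11-bp
    direct repeats (consensus nnnnTnnACAn) in promoter windows extracted
    from genome FASTA/GFF3; models cooperative binding of repressor dimers
    to repeat arrays to predict gel-shift band categories and DNase I,
    hydroxyl-radical and exonuclease III footprint geometry; fits EMSA
    titrations with a three-parameter Hill equation; converts
    size-exclusion chromatography elution volumes to apparent molecular
    mass and oligomeric state; and normalizes qRT-PCR expression. Seeded
    synthetic-data generators with recorded ground truth make every stage
    testable without genome downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    minpack.lm,
    pracma,
    withr,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
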