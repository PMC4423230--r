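Package: cnelink
Title: Conserved Noncoding Elements and Evolutionary Linkage to Target Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects conserved noncoding elements (CNEs) in multi-species
    alignment blocks (MAF) with exon and repeat masking, scores the
    evolutionary maintenance of linkage between each CNE and its candidate
    target genes across vertebrate genomes (the S_A linkage score, built
    from per-species gene status, conserved synteny and sequencing-coverage
    corrections), fuses co-targeting CNEs into regulatory elements,
    quantifies coverage-weighted overlap with functional signal tracks, and
    tests the consistency of target predictions against promoter
    interaction pairs with a window-resampling permutation null. Ships a
    synthetic rearranged-genome generator with full ground truth so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
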