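Package: MitoRearr
Title: Gene-Arrangement Analysis of Insect Mitochondrial Genomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing gene arrangements in annotated insect
    mitochondrial genomes. Reads GenBank flat files into circular annotated
    genome objects, extracts signed circular gene orders, classifies
    arrangement types against the ancestral insect gene order, quantifies
    rearrangement with per-gene rearrangement scores and cohort-level
    rearrangement frequencies (qMGR-style adjacency scoring), infers minimal
    tandem-duplication-random-loss, inversion and transposition event
    histories, and computes nucleotide composition statistics (AT/GC skew,
    relative synonymous codon usage) and pairwise Ka/Ks under Nei-Gojobori
    (1986) counting with Jukes-Cantor correction. Includes a fully seeded
    synthetic-data generator for annotated records, gene-order cohorts with
    known event histories, and codon alignments with controlled divergence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
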