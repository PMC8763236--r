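Package: isburst
Title: Detection and Population Dynamics of Insertion Sequence
    Transposition Bursts in Bacterial Laboratory Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying bursts of insertion sequence (IS)
    transposition during bacterial laboratory evolution. Provides a
    transposase census with paralog clustering and Nei-Gojobori dN/dS
    dating of duplicated element copies, ambiguity-aware expression
    quantification for clusters of near-identical paralogs, a split-read
    junction caller for new IS insertions in mixed-population sequencing
    with allele-frequency estimation and strand/quality bias tests,
    allele-frequency trajectory analysis across serial-transfer
    populations (fixation, parallelism, clonal interference, Muller
    tables), and two-phase exponential/linear growth-curve fitting.
    Includes synthetic-data generators (genomes with planted IS copies,
    copy-and-paste transposition with target-site duplications,
    Wright-Fisher serial-transfer simulation, short-read and stranded
    RNA-seq read simulators, growth curves) so every stage can be
    validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
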