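Package: orgkit
Title: Structural and Editing Analysis of Plant Organelle Genomes
Version: 0.1.0
Authors@R:
    person("orgkit", "developers", email = "orgkit@example.org", role = c("aut", "cre"))
Description: Toolkit for characterizing plant organelle genomes: dispersed
    direct/inverted repeat discovery and size-class summaries, detection of the
    plastome's reduced inverted-repeat pair and its single-copy partitions,
    scanning a mitogenome for plastid-derived fragments (MIPTs), open reading
    frame and chimeric-ORF detection, empirical C-to-U RNA-editing calling from
    RNA-seq pileups with codon-consequence classification, plastome isomer
    (form A/form B) construction and long-read classification, ancestral
    gene-cluster retention and cis/trans intron classification, supermatrix
    concatenation with partition bookkeeping, Robinson-Foulds topology
    comparison, and the pairwise homoplasy index (PHI) recombination test.
    Includes seeded synthetic-data generators with ground truth for end-to-end
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
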