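Package: indelphase
Title: Phylogenetic Detection of Accelerated Insertion and Deletion Rates
Version: 0.1.0
Authors@R:
    person("indelphase", "developers", email = "indelphase@example.org",
           role = c("aut", "cre"))
Description: Fits gap-extended nucleotide substitution models (F84, HKY with
    gap as a fifth character, and a relaxed indel extension of F84 with
    per-site insertion and deletion rates and a geometric ancestral-length
    prior) across sets of gene-family alignments, and tests each alignment
    column for acceleration or conservation of the indel rate independently
    of the nucleotide substitution rate via per-column likelihood-ratio
    tests.  Includes marginal ancestral reconstruction with
    implicit-parsimony counting of insertion and deletion lengths, a forward
    simulator over the gap-extended alphabet with recorded event truth, and
    a command-line interface covering filtering, fitting, scoring, event
    counting and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Matrix,
    Biostrings,
    data.table,
    jsonlite,
    rlang,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
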