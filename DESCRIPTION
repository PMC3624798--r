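Package: pairprob
Title: Probabilistic Pairing of Paired-End Read Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates, for every candidate local alignment of a paired-end
    sequencing read, the marginal posterior probability that the alignment
    represents the read's true genomic source. Candidate alignments are
    produced by any local aligner whose integer scores are scaled
    log-likelihood ratios; this package fits the fragment-length
    distribution robustly from the candidates themselves (normal for DNA,
    log-normal for RNA), combines alignment scores with a conjoint/disjoint
    pairing prior, and corrects for the aligner's score cutoff, missing
    mates and circular chromosomes. Includes readers and writers for MAF,
    a 12-column tabular alignment dialect and SAM, a seeded synthetic
    paired-end data generator with per-base quality-profile errors, and an
    accuracy/error threshold-curve evaluator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
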