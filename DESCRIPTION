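Package: ampshower
Title: Simulation and Analysis of Stress-Induced Gene Amplification and
    Genome-Wide Structural Instability
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to simulate and analyse stress-induced gene amplification
    and associated chromosomal structural instability in a bacterial
    chromosome plus F'-like episome system. Builds synthetic circular
    reference replicons with a tiling oligonucleotide probe array, constructs
    template-switch rearrangements (tandem amplification, embedded inverted
    duplications, partially inverted amplifications, embedded and unlinked
    deletions, inversions with endpoint micro-indels) as oriented segment
    plans, simulates array-CGH log2 ratios, calls copy-number segments with
    an adjacent-probe threshold rule, classifies event structures, measures
    breakpoint junction microhomology, annotates REP-element overlap,
    performs in-silico unidirectional PCR inversion screens, predicts DNA
    stem-loop structures from inverted repeats, and computes exact 2x2
    cohort statistics (Fisher's exact test and the Peto one-step odds ratio
    with confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: CopyNumberVariation, StructuralVariation, aCGH, Sequencing,
    Software
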