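Package: MotifTriad
Title: Three-Engine Transcription Factor Motif Consensus for LPS-Tolerance
    Expression Phenotypes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies macrophage genes from three-condition (naive,
    LPS-stimulated, tolerized-and-restimulated) expression matrices into
    pro-inflammatory (tolerizable) and antibacterial (non-tolerizable)
    phenotypes, then predicts the transcription-factor binding motifs that
    discriminate them by intersecting three independent engines: de novo
    expectation-maximization motif discovery under a zero-or-one-occurrence
    (ZOOPS) model, an iterated linear model of expression on motif occurrences
    yielding a transcription contribution score, and a binding-affinity /
    condition-specificity association scored by an iterated hypergeometric
    test. Includes top-70 percent per-engine selection, ungapped
    column-correlation matching of de novo motifs to a TRANSFAC-style matrix
    library, random-gene background contrasts, literature-target pattern
    validation, and a seeded synthetic-data generator with a ground-truth
    manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: GeneExpression, MotifDiscovery, Transcription, Software
LinkingTo:
    Rcpp
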