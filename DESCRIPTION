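Package: bindscape
Title: Binding Landscapes for RNA Pull-Down Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of protein-RNA pull-down (RIP-seq style)
    experiments in bacteria, built around the question of whether cold shock
    proteins preferentially bind uracil-rich, membrane-protein-encoding mRNAs.
    Provides RPKM normalisation and per-gene binding scores
    (RPKM pull-down / RPKM extract), percentile "binding landscape" construction
    with per-decile category quotas and hypergeometric / EASE enrichment tests,
    sliding-window uracil-content profiling and design of untranslatable model
    transcripts (start-codon removal, stop-codon decoration, Shine-Dalgarno
    disruption), qPCR cycle-threshold arithmetic (fraction ratios, relative
    quantities against an endogenous control, standard-curve QC), and a
    negative-binomial synthetic-data generator so every stage of the pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
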