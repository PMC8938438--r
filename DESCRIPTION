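Package: perturbMPRA
Title: Design and Analysis of Perturbation Massively Parallel Reporter Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for perturbation massively parallel reporter
    assays (MPRA) over a differentiation time course: integer-linear-program
    based selection of region and motif combinations from a tripartite design
    graph, construction of perturbation oligo libraries (fixed "non-motif"
    replacement and nucleotide-shuffle designs, with scrambled and random-window
    controls), barcode-to-sequence association and count assembly, transcription
    rate ("alpha") estimation with nested gamma/negative-binomial generalized
    linear models, four-filter calling of functional regulatory sites with
    activator/dampener categorization, activation-dynamics fitting, and
    pairwise motif-interaction testing against a log-additive null. A
    synthetic-data generator with planted ground truth makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
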