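Package: MCPtriage
Title: Functional Triage and Selection Analysis of Duplicated
    Metallocarboxypeptidase Paralogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing recently duplicated genes of the M14
    metallocarboxypeptidase (MCP) family. Predicted paralog proteins are
    mapped onto the bovine CPA1 residue-numbering convention by global
    alignment, triaged into active enzymes, pseudoenzymes and pseudogenes
    from an active-site and structural-residue inventory, and assigned a
    predicted C-terminal substrate-specificity class from the residue-255
    equivalent at the base of the S1' pocket. Paralog pairs are compared
    with a from-scratch Nei-Gojobori estimator of synonymous and
    nonsynonymous substitutions per site (Jukes-Cantor corrected,
    analytical variances) and a one-tailed codon-based Z-test of purifying
    selection (dN < dS). Cohort-level utilities detect tandem gene arrays
    from locus tables and compare gene-size distributions between
    frequently-duplicated and other genes. A synthetic-cohort generator
    produces scheme-compliant coding sequences, truth-labelled paralog
    families, omega-controlled divergent pairs and locus layouts so that
    every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
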