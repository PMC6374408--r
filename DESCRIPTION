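Package: coexcand
Title: Candidate Gene Prioritization from Co-Expression Networks and
    Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate biosynthesis genes by combining replicated
    two-genotype differential-expression calling on an FPKM matrix (with
    value-level flooring at 1 and nested log2 fold-change thresholds) with
    three prioritization approaches over a weighted functional co-expression
    network: guide-gene scoring by summed log-likelihood edge scores,
    differentially-expressed-gene seeded scoring, and hub-neighborhood
    hypergeometric enrichment. Rankings are integrated into a multi-approach
    candidate table and validated against qRT-PCR data via 2^-ddCt relative
    quantification and sign concordance. Includes a planted-module synthetic
    data generator so the whole pipeline is testable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
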