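Package: mitoscreen
Title: Group-Query Screening for Candidate Mitosis Regulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Guilt-by-association prioritization of candidate mitosis
    regulators using a group of centromere/kinetochore genes as a collective
    query. Implements rank-based top-K co-expression neighbour extraction and
    pooled occurrence counting across an ensemble of expression datasets,
    mutual-rank co-expression scoring, protein-protein-interaction sub-network
    specificity (S3) scoring against a random-group empirical null,
    permutation Z-score enrichment of target gene sets, and intersection of
    co-expression and interaction evidence. Ships transcriptions of the
    published query and result tables as fixtures, and a synthetic-data
    generator with planted co-expression modules and interaction clusters so
    every pipeline stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
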