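Package: docmatch
Title: Full-Document Semantic Comparison by Piecewise Chunk Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares long, paged documents (such as regulatory assessment
    reports and scientific guidelines) by splitting each document into
    overlapping fixed-size word chunks, embedding every chunk as a unit-norm
    vector, and aggregating all-vs-all chunk cosine distances into a global
    document distance: the mean of the N lowest chunk distances, where N is
    the chunk count of the smaller document. Includes a mean-pooling
    comparator, corpus-level scoring against the best-matching fraction of a
    reference corpus, group-specificity scores adjusted by the global
    geometric mean, and linear-regression analysis of distance scores against
    normalised product covariates. Ships a deterministic mock encoder and a
    seeded synthetic corpus generator so the whole pipeline is testable
    offline, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    stringi,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
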