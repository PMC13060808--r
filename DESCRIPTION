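Package: rescuerank
Title: Homolog Ranking and Literature-Mined Protocol Rescue for Failed
    Protein Purifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ranks homologs of a protein that failed purification by a
    composite of normalized sequence identity and rank-penalized taxonomy-tree
    distance, mines purification protocols from full-text JATS XML articles,
    normalizes them into a standardized six-column protocol table
    (purification step, buffer name, buffer composition, pH, salt type,
    buffer supplement), and produces an optimization report that diffs the
    failed protocol against successful ones with confidence-labelled
    recommendations. Ships a deterministic rule-based extraction backend and
    a synthetic-fixture generator so the whole pipeline runs and is tested
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
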