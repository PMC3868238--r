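Package: kinconn
Title: Connectivity Mapping of Kinase Inhibitor Selectivity Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rank-based connectivity scoring of kinase inhibitors against a
    query set of kinases. Converts a quantitative drug-by-kinase activity
    matrix (percent inhibition or dissociation constants) into rank-ordered
    reference profiles, scores every inhibitor with a Kolmogorov-Smirnov
    style enrichment statistic and a normalized connectivity score, and
    attaches permutation p-values. Includes query expansion by kinase family
    or Gene Ontology term, a synthetic-profile simulator for testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
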