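Package: patternet
Title: Time-Course Expression Pattern Grouping and Network Centrality Gene Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate genes from a paired three-timepoint expression
    experiment (control, treatment, withdrawal) by classifying genes into six
    fold-change trajectory groups, inducing a functional-association network on
    the patterned genes from a STRING-style interaction table, ranking nodes by
    shortest-path betweenness centrality, quantifying within- versus
    between-group link enrichment against random-labeling nulls, and testing a
    curated gene set for over-representation in the top centrality tier with a
    hypergeometric test. Includes a synthetic-data generator (log-normal
    expression with planted trajectory groups and a stochastic block model
    interaction network) so every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
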