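Package: agonet
Title: Significant Dyads and Agonistic Social Networks in Group-Housed Pigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how restricting agonistic-interaction networks to
    dyads with a significantly asymmetric win/loss outcome changes the results
    of social network analysis in newly mixed pig groups.  Provides exact
    sign-test classification of dyads under pen-level and dyad-level limits,
    construction of directed initiator-to-receiver networks, general network
    and centrality parameters for directed graphs with isolates, expanding
    time-window analysis anchored at mixing, rank-based comparisons between
    the resulting data sets, and a stochastic generator of agonistic
    event logs with a latent dominance hierarchy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr,
    xml2
Config/testthat/edition: 3
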