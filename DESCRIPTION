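Package: contactseq
Title: Event Mapping and Contact Sequence Centrality for Temporal Contact Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing timestamped pairwise contact data as temporal
    networks. Contacts are binned into snapshots, connected components within each
    snapshot become 'events', and events are linked across consecutive snapshots
    through shared participants, yielding a time-directed event graph. On this
    representation the package computes time-respecting traceability P(j,t,dt)
    (the fraction of agents reachable from an agent through contact sequences),
    its population mean, and contact sequence centrality C(i,t,dt): the drop in
    mean traceability when all temporal links of one agent are removed, a
    leave-one-out impact measure that identifies behavioural super-spreaders.
    Also included are classical comparison metrics (aggregated degree, contact,
    event and temporal betweenness, event participation), Spearman correlation of
    degree with centrality across time scales, parameterised synthetic
    temporal-network generators, and readers/writers for delimited contact logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
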