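Package: c2cards
Title: Consensus and Conflict Cards for Metabolic Pathway Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes independently curated metabolic-network descriptions of
    one organism and quantifies their reaction-level agreement. Genes,
    metabolites and EC numbers are matched across databases by identifier
    cascades with transitive closure; reactions are compared by a side-respecting,
    direction-ignoring percentage-of-overlap statistic with currency metabolites
    (e-, H+, H2O) excluded. Results are assembled into consensus-and-conflict
    cards centered at a gene, EC number or reaction, plus corpus-level tools for
    metabolite fate, dead-end detection, pathway membership and per-database
    content statistics. Includes deterministic synthetic-corpus generators with
    ground truth and hand-coded mini-corpora for well-known conflict scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
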