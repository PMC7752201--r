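Package: pte
Title: Participatory Theme Elicitation from Card-Sorting Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of participatory theme elicitation (PTE), a
    network-based approach to participatory qualitative analysis. Independent
    card sorts of quotes are combined into a weighted co-occurrence network,
    quote groupings are detected by Louvain modularity maximization, and
    theme-level congruence statistics (dominant-grouping percentages,
    adjusted Rand index, theme overlap matching) quantify agreement between
    analyst groups. Includes a seeded generator of synthetic sorting studies
    with planted theme structure for recovery experiments, and a command-line
    interface covering the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
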