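Package: trialnet
Title: Country Co-Participation Networks from Clinical Trial Registries
Version: 0.1.0
Authors@R: person("trialnet", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds weighted country co-participation networks from clinical
    trial registry records. Each multinational study contributes one
    connection per unordered pair of participating countries; connections are
    accumulated into a weighted edge list and an integrated network with
    weighted node totals. On top of the network the package computes
    connectivity summaries (total connections, per-country and per-region
    weighted totals and shares, cross-region share, strongest edges),
    regional study-participation proportions, temporal trend statistics
    (studies per year, year-over-year and annualized growth, peak year), and
    condition-by-region tables. A seeded synthetic registry generator with
    known ground truth supports testing every pipeline stage offline, and a
    command-line interface ties the stages into a reproducible end-to-end
    analysis with Gephi-compatible exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
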