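Package: aftsim
Title: Agent-Based Simulation of Land-Use Competition for Ecosystem Services
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stylised agent-based land-use model in which agent functional
    types (land managers such as farmers and conservationists) compete for
    grid cells to supply ecosystem services (food and recreation) in response
    to exogenous demand. Production follows a Cobb-Douglas mapping from
    per-cell capitals (crop productivity, natural capital); behaviour is
    governed by abandonment and competition thresholds, stochastic cell
    search with ranked takeover attempts, and linear or exponential benefit
    functions of unmet demand. Ships a catalogue of globalisation versus
    regionalisation experiments, seeded ensemble runs, and diagnostics for
    steady-state detection, land-use composition, capital-space occupancy,
    abandonment patterns and land-use concentration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
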