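Package: landes
Title: Land-Use Change Scenarios and Ecosystem-Service Trade-Offs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Couples a Markov-chain / cellular-automata land-use change
    simulator (neural-network suitability surfaces, self-adaptive inertia
    and competition allocation, scenario constraints, figure-of-merit
    validation) with per-pixel models of six ecosystem services: carbon
    storage, flood regulation via Budyko-curve annual water yield, soil
    conservation (RKLS minus USLE), nitrogen export over D8 flow paths,
    habitat quality under distance-decayed threats, and district-level crop
    production. Service surfaces are min-max standardized, combined into a
    weighted sum-of-ecosystem-services indicator, and trade-offs and
    synergies are quantified by rank correlation over random sample points.
    Includes a fully synthetic landscape generator so the whole pipeline is
    testable without external spatial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    nnet,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
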