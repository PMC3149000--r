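Package: coliflux
Title: Metabolic Flux Analysis of Escherichia coli Continuous Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stoichiometric metabolic flux analysis (MFA) for Escherichia coli
    K-12 MG1655 continuous cultivations (chemostat, accelerostat/A-stat and
    D-stat). Converts culture time series into specific rates, solves a fully
    determined central-carbon-metabolism flux model with growth-rate-dependent
    biomass drains and cofactor (ATP/NADH/NADPH) balancing, and summarises
    carbon balance closure, by-product carbon wasting and ATP spilling
    (non-growth-associated ATP dissipation). Includes a synthetic A-stat/D-stat
    scenario generator with exact ground-truth flux vectors for end-to-end
    validation, plus readers/writers for the network, composition and
    time-series text formats and an SBML exporter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    xml2
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
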