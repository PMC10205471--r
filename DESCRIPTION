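Package: hgtrade
Title: Trade-Linked Mercury Emissions, Exposure and Health Impact Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to trace anthropogenic mercury from economic production to
    human health across a multiregional economy. Implements environmentally
    extended multiregional input-output (MRIO) accounting of emissions embodied
    in international trade, a counterfactual "no trade" gridded emission
    scenario, a linear source-receptor transport surrogate with a
    latitude-dependent deposited fraction, proxy-scaled dietary methylmercury
    exposure, IQ-decrement and fatal-heart-attack health endpoints with
    economic valuation, and Monte Carlo uncertainty propagation. Ships a
    synthetic-world generator so the full chain is testable without external
    data.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
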