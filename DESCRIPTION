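Package: walrisk
Title: Harvest-Risk Assessment for the Smith Sound Walrus Stock
Version: 0.1.0
Authors@R:
    person("Assessment", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for risk-based catch advice for a hunted Atlantic walrus
    stock. Reconstructs total removals from sparse catch records with
    struck-and-lost and underreporting corrections, collapses life-history
    priors into a maximum per-capita growth rate via the Euler-Lotka
    equation, fits a density-regulated (Pella-Tomlinson) surplus-production
    model to abundance surveys by sampling-importance-resampling, projects
    the stock five years forward under candidate catch levels, and advises
    the largest quota meeting a probability-of-increase criterion.
    Includes a synthetic-data generator with known truth for end-to-end
    testing and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
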