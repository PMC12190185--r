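Package: kneeload
Title: Decomposition of Tibiofemoral Contact Loads into External, Muscle,
    and Ligament Contributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quasi-static decomposition of knee (tibiofemoral) compartment
    contact loads during the stance phase of gait. Implements a piecewise
    nonlinear-elastic ligament model (10 ligaments, 22 bundles), a two-point
    medial/lateral contact joint with frontal-plane moment-balance
    attribution of each external, muscle, and ligament force source, a
    reduced quasi-static inverse-mechanics model with static-optimization
    muscle recruitment, a seeded synthetic gait generator emulating healthy
    and medial knee-osteoarthritis cohorts, stance sub-phase percent
    contribution summaries, and group-comparison statistics with
    Benjamini-Hochberg false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
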