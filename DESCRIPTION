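Package: screenmix
Title: Empirical-Bayes Mixture-Model Analysis of Arrayed Colony-Fitness Screens
Version: 0.1.0
Authors@R: person("screenmix", "maintainers", email = "screenmix@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing genome-wide arrayed colony-fitness screens
    (e.g. Synthetic Physical Interaction screens in budding yeast): plate
    normalization of colony sizes, log growth ratio (LGR) computation with
    two-control averaging, windowed-median spatial smoothing, Z-transformation,
    two-component Gaussian mixture fitting by expectation-maximization,
    posterior hit-probability cutoffs, validation-rate and false-positive-rate
    prediction, cross-screen parameter comparison and correlation-distance
    clustering, plus a plate-level screen simulator with ground truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    ape,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
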