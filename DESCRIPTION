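Package: chevronfit
Title: Chevron-Plot Global Fitting and Phi-Value Analysis of Protein Folding Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing stopped-flow (un)folding kinetics of small
    globular proteins. Extracts observed rate constants from single-exponential
    fluorescence time courses, fits chevron plots (log k_obs versus denaturant)
    to a three-state rate law with an on-pathway high-energy intermediate,
    performs global (shared m-value) fits across site-directed variants, and
    derives the downstream thermodynamic analyses: Phi-values for early and
    late transition states with category labels, beta-Tanford values, linear
    free-energy relationships (alpha values), Hammond-effect regressions of
    beta against stability, and Phi-vs-Phi comparison between homologous
    domains. Includes a seeded synthetic-data generator emulating the
    stopped-flow experimental design, and a packaged reference table of
    published kinetic parameters for an SH2 domain used as a verification
    dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
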