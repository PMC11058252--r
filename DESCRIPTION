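Package: colimfit
Title: Light-Nitrogen Colimitation Analysis of Microhabitat Array Growth
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of algal growth experiments in
    gradient microhabitat arrays where rows carry a nitrogen gradient and
    columns a light (PAR) gradient. Provides a family of Monod-type
    colimitation growth models (multiplicative with storage terms, reduced
    multiplicative, law-of-minimum, and a generalized n-factor product
    form), a synthetic-data generator for replicate array time series,
    sliding-window extraction of maximum specific growth rates from
    log-transformed fluorescence curves, weighted-bootstrap nonlinear
    least-squares parameter estimation with uncertainty and model
    comparison, and growth-rate prediction maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
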