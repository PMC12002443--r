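Package: pbtksim
Title: Generic Physiologically Based Toxicokinetic Modeling and In
    Vitro-In Vivo Extrapolation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained framework for high-throughput toxicokinetics
    (HTTK): management of chemical-specific physico-chemical and in vitro
    measurement libraries, tissue:plasma partition coefficient prediction by
    a Schmitt-type component model, parameterization of a suite of generic
    toxicokinetic models (one-compartment, steady-state three-compartment,
    perfusion-limited PBTK, and a gas-inhalation PBTK with alveolar
    equilibration), an event-driven stiff ODE simulation core with a model
    registry contract and mass-balance checking, analytic and numerical
    quasi-steady-state plasma concentrations, four-step Monte Carlo
    propagation of uncertainty and population variability with
    reverse-dosimetry in vitro-to-in vivo extrapolation, and a benchmark and
    evaluation suite based on root mean squared log10 error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
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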