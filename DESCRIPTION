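Package: nitrikin
Title: Nitrification Kinetics from Incubation Time Series by Boltzmann Curve Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates ammonia-oxidation and nitrite-oxidation potential rates
    from dissolved-inorganic-nitrogen (DIN) incubation time series. Cumulative
    oxidized-nitrogen series (nitrite+nitrate for ammonia oxidation, nitrate for
    nitrite oxidation) are fitted with the four-parameter Boltzmann sigmoid;
    average rates are computed from fitted endpoint concentrations and
    instantaneous rate curves from the analytic first derivative, together with
    lag/exponential/plateau phase boundaries and the index of nitrogen balance
    (INB) diagnostic for net nitrogen loss or mineralization. A two-step
    nitrification ODE simulator with Monod kinetics, induction ramps, nitrogen
    loss and mineralization generates seed-reproducible synthetic incubations
    with known ground truth for validation, and a pipeline runner ties
    simulation, fitting, rate calculus and reporting into reproducible run
    directories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
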