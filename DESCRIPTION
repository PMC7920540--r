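Package: thalamod
Title: Biophysical Modelling of Motor Thalamic Neuron Excitability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based multicompartment modelling of ventromedial
    (motor) thalamocortical neurons, with in-silico current-clamp protocols
    and the intrinsic-excitability feature extraction used in slice
    electrophysiology.  Builds surrogate or SWC-derived morphologies with
    Rall-rule dendritic diameters, distributes ten Hodgkin-Huxley-style
    conductances (including an M-type potassium current and a T-type calcium
    current) over the tree, integrates the cable equations with an implicit
    solver, and measures rheobase, F-I curves, sag, rebound bursting and
    passive properties from the simulated traces.  Includes a Henderson
    liquid-junction-potential calculator and a synthetic-cohort generator for
    control versus M-current-depleted populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
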