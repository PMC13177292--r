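Package: dynchrom
Title: Dynamic Chiral Chromatography: Stochastic Peak Models and
    Phase-Specific Enantiomerization Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing on-column enantiomerization in chiral
    HPLC ("Batman" peaks). Implements the unified equation for
    interconversion rate constants from peak descriptors, one- and
    two-site stochastic (characteristic-function) peak models with
    Keller-Giddings interconversion densities and a Monte-Carlo
    cross-check, two-stage differential-evolution / Levenberg-Marquardt
    profile fitting, competitive bi-Langmuir isotherm estimation from
    overload chromatograms via an equilibrium-dispersive column model,
    decomposition of apparent rates into mobile- and stationary-phase
    contributions by inverse-variance pooling and weighted linear
    mixed-effects modelling, weighted Eyring-Polanyi and Arrhenius
    activation thermodynamics, validation against off-column circular
    dichroism racemization kinetics, and a global empirical-Bayes (MAP)
    model with Laplace uncertainty. Includes a synthetic-data generator
    emulating a multi-column, multi-eluent, multi-temperature design
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    lme4,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
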