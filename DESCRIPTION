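Package: kinesim
Title: Chemomechanical Coupling Kinetics of Kinesin Molecular Motors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical and stochastic modelling of the coupling between ATP
    hydrolysis and mechanical stepping in dimeric kinesin motors. Provides
    closed-form force and ATP dependence of velocity, stepping ratio, dwell
    time, diffusion constant, randomness parameter, ATP consumed per step,
    power, and efficiency for wild-type and extended-neck-linker kinesins at
    saturating ATP; a seedable stochastic stepping simulator (fixed-timestep
    and exact event-driven engines) for non-saturating ATP; optical-trap-style
    bead-trace construction and step detection; and nonlinear least-squares
    estimation of the kinetic parameters from force-velocity or stepping-ratio
    data, with a synthetic-data generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
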