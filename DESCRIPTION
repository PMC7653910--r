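Package: seirshape
Title: Semi-Analytic SIR and SEIR Epidemic Curves and Their Universal Time Scaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact semi-analytic solutions of the SIR compartmental epidemic
    model and approximate semi-analytic solutions of the SEIR model, obtained by
    reducing the susceptible equation to a Bernoulli differential equation. The
    SEIR solution implies that epidemic curves with different incubation and
    infectious periods are stretched copies of one another with stretch factor
    alpha = sigma/(sigma + gamma), so that the scaled time to the infectious
    peak, alpha*gamma*dt, depends (approximately) only on the basic reproduction
    number and the initial infectious fraction. The package provides the
    compartment-vs-susceptible closed forms, the one-quadrature time integral,
    peak-time and growth-rate relations, a high-accuracy ODE reference
    integrator, and seeded ensemble experiments that quantify the curve collapse
    and peak-time universality, with tidy tibble outputs and ggplot2 graphics.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
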