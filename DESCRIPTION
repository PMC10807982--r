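Package: turnlearn
Title: Cultural Evolution Under Population Turnover and Behavioral
    Conservatism
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compartmental model of social learning in a group facing a
    task with an efficient and an inefficient solution, under continuous
    population turnover that replaces individuals of any state with naive
    newcomers. Provides exact evaluation of the mean-field right-hand
    side, adaptive ODE integration with event detection for
    time-to-adoption metrics, closed-form and numerical equilibrium
    analysis with regime classification, parameter-space sweeps including
    the critical curve where turnover neither accelerates nor slows
    adoption and the critical social-learning/turnover ratio, a
    drift-exact finite-population continuous-time Markov chain
    counterpart for validation, and a command-line interface with CSV
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    graphics,
    grDevices,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
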