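Package: vestibsim
Title: Desk-Scale Simulator for Ramped-Pulse Vestibular Afferent Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates charge-balanced rectangular and ramped biphasic current
    pulses and pulse-frequency-modulated trains, propagates them through an
    analytic volume-conductor and multicompartment cable models of vestibular
    afferents in a procedurally generated labyrinth, synthesizes electrically
    evoked compound action potentials (eCAPs) by reciprocity, and scores pulse
    shapes by threshold, growth-function slope, dynamic range, and predicted
    vestibulo-ocular reflex axis misalignment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
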