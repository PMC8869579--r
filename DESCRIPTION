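Package: lovewave
Title: Modelling and Signal Processing for Love-Wave Delay-Line Sensors in Liquid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for Love-wave (shear-horizontal
    surface acoustic wave) delay-line sensors operated under viscous liquid
    loading. Implements an acoustic transmission-line model of the layered
    waveguide with a transverse-resonance dispersion solver, the Campbell
    cross-field circuit model of interdigital transducers, penetration-depth
    design rules, glycerol-water calibration-liquid property correlations,
    Touchstone two-port S-parameter input/output, time-domain gating, and
    sensorgram extraction (minimum insertion loss and fixed-frequency phase).
    A synthetic-spectrum generator emulates a vector-network-analyzer
    acquisition so every processing stage is testable without measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
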