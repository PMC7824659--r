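Package: moverstayer
Title: Mover-Stayer Markov Models of Intra-Urban Relocation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models intra-urban residential relocation in a closed system as a
    diffusive relaxation process. Provides the mover-stayer decomposition of
    origin-destination relocation matrices P = (1-eps)I + eps*H, estimation of
    the destination-choice kernel H from flow tables, prediction of the
    equilibrium (stationary) population distribution, multi-component mixtures
    with distinct relocation frequencies, calibration of two-component
    frequencies from one-year and five-year stayer shares, spectral relaxation
    diagnostics, a refractory (immobility) rival model, synthetic toy-city
    generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
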