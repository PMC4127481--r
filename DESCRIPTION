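Package: pollentube
Title: Integrative Modeling of Pollen Tube Tip Growth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates oscillatory pollen tube tip growth by coupling
    hydrodynamics (osmotic water flow through a fixed tip osmotic zone),
    Lockhart-type cell wall mechanics with calcium-dependent vesicle
    secretion, and the dynamics of four cellular ions transported by
    voltage-gated and turgor-gated stretch-activated channels. Includes a
    scenario engine for osmotic, ionic, wall-viscosity and membrane
    trafficking perturbation protocols, limit-cycle period and amplitude
    analysis with exact-period averaging, regulation-coefficient
    decomposition of growth control between two oscillatory states, and a
    seeded calibration workflow that recovers working parameter sets from
    experimental constraints.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    yaml,
    jsonlite,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
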