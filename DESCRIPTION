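Package: ionpmf
Title: Umbrella-Sampling Unbiasing, Minimum Free-Energy Paths and Kramers
    Rate Chains for Ion Permeation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for ion-channel permeation energetics from
    umbrella-sampling data: reads COLVAR-style window time series, unbiases
    them into 1D/2D potentials of mean force with the weighted histogram
    analysis method (WHAM), locates free-energy minima on interpolated
    surfaces, extracts minimum free-energy paths with the nudged elastic
    band method, joins and ranks candidate conduction paths, projects them
    onto a 1D reaction coordinate, and converts barrier profiles into
    relative conduction rates via overdamped Kramers theory chained through
    a linear ODE system with an absorbing final state. Includes a synthetic
    free-energy-landscape generator with exactly known minima and saddles so
    every stage can be validated against analytic ground truth, plus
    transition-state-theory conversions between unitary conductance,
    transition rates and effective barriers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
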