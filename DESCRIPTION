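Package: cargoflip
Title: Stochastic Intra-Carrier Cargo Transfer Between Two Compartments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the stochastic kinetics of cargo exchange between the two
    compartments of an ensemble of nanocarriers, such as amphipathic drug
    molecules flip-flopping between the inner and outer leaflets of a lipid
    vesicle. Implements the combinatorial chemical master equation over carrier
    occupancy states and its numerical integration with conservation-aware state
    truncation, the detailed-balance equilibrium (product-binomial within each
    fixed-total-cargo subpopulation), the analytic Fokker-Planck solution in the
    Gaussian low-occupation limit via an Ornstein-Uhlenbeck-type Green's
    function, the full moment algebra, closed-form worked examples, and an exact
    per-carrier Gillespie simulator that serves as an independent oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
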