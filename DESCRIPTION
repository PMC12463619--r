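Package: aggnmr
Title: Kinetic Modelling of Amyloid Pre-Nucleation, Aggregation and
    Inhibition from Solution-NMR Observables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward models and global-fitting tools for the early stages
    of amyloid aggregation as probed by solution-state NMR, developed
    around the huntingtin exon 1 system. Implements a branched
    pre-nucleation mass-action equilibrium (monomer, productive dimer,
    off-pathway dimer, tetramer, optional monomer-inhibitor complex),
    Bloch-McConnell simulators of exchange-induced chemical shifts, CPMG
    and on-resonance R1rho relaxation dispersion, a
    nucleation-elongation ODE cascade with secondary nucleation and four
    inhibitor-binding schemes, time-resolved observables (PRD intensity
    decay, cross-peak volume/intensity ratios, time-dependent chemical
    shifts), synthetic data generation, and global fitting with
    AICc-based classification of inhibitor mechanisms (monomer versus
    nucleus sequestration).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
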