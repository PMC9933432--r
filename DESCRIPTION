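Package: grandmc
Title: Grand Canonical and Nonequilibrium Candidate Monte Carlo Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A self-contained simulator for grand canonical Monte Carlo
    (GCMC) and grand canonical nonequilibrium candidate Monte Carlo
    (GCNCMC) sampling of small rigid molecules, aimed at the enhanced
    sampling of buried solvent sites. Provides soft-core alchemical
    nonbonded interactions, BAOAB Langevin dynamics with rigid-body
    distance constraints, instantaneous and gradual (nonequilibrium)
    insertion and deletion moves in a spherical or whole-box region,
    campaign drivers alternating Monte Carlo with molecular dynamics, and
    analysis tools for occupancy distributions and hydration-site
    clustering against reference coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
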