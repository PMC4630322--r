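Package: avasim
Title: Multiscale Agent-Based Simulation of Avascular Tumor Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Lattice-free multiscale simulator of avascular tumor growth. Five
    biochemical species (oxygen, glucose, metabolic waste, growth factors and
    growth inhibitors) diffuse over a discretized domain with Dirichlet
    boundaries and per-cell source/sink coupling, while an off-lattice cell
    population evolves under an ATP-denominated health function built on the
    Warburg two-pathway glucose metabolism. Includes stochastic mitosis with a
    Hayflick limit, cancer-stem-cell seeding, spring-based differential
    adhesion, chemotaxis, a logistic/hazard (Gillespie-style pure birth)
    population reduction with sigmoid curve fitting, and morphology analysis
    of the emergent necrotic, mixed and quiescent tumor regions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
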