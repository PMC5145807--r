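Package: poreannotate
Title: Functional Annotation of Ion Channel Pore Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Functional annotation of ion-channel structures as conductive or
    non-conductive based on the physics of hydrophobic gating. Implements a
    three-level analysis hierarchy: HOLE-style pore-radius profiling with a
    simulated-annealing probe sphere; water-density analysis of pore hydration
    (axial tracks, dewetted fraction, permeation flux, Boltzmann-inversion
    free-energy profiles, ion hydration numbers); weighted-histogram (WHAM)
    reconstruction of single-particle potentials of mean force from
    umbrella-sampling windows with bootstrap errors and convergence
    diagnostics; and computational-electrophysiology post-analysis (charge
    density, transmembrane potential by Poisson double integration,
    compartment bookkeeping, ion-crossing counts). A synthetic module
    generates model pores, Metropolis-sampled water trajectories on
    prescribed 1-D potentials, umbrella windows, and charged-slab frames so
    every stage can be exercised and validated without molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
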