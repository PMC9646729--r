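Package: bandfib
Title: Design and Multiscale Simulation of Synthetic Banded-Fiber Collagens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing synthetic collagens that self-assemble into
    banded fibers and for simulating that assembly across scales. Designed
    chains are built from a module grammar (terminal adhesive triplet blocks
    flanking a tailorable functional-driver block), band geometry is predicted
    from residue counts and the collagen helical rise, inter-helix association
    is ranked by a discrete sliding-stagger contact score and by rigid-body
    Lennard-Jones/Coulomb packing energetics optimized with Monte Carlo
    simulated annealing, and supramolecular fiber growth is simulated by
    diffusion-limited aggregation of coarse-grained rods on a 3D hexagonal
    lattice. Banding periodicity of simulated or measured intensity traces is
    estimated by Fourier and real-space methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    bio3d,
    Biostrings,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
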