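Package: poresim
Title: Voxel-Graph Simulation of Microbial Decomposition in Soil Pore Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates microbial decomposition of organic matter in the
    water-filled pore space of soil, resolved at the voxel scale of binary 3D
    computed-tomography images. Pore voxels form a 6-connected graph on which
    dissolved organic matter diffuses by a graph-Laplacian form of Fick's law
    (explicit or implicit Euler, with a Jacobi-preconditioned conjugate
    gradient solver), coupled by operator splitting to a five-pool
    Monod-kinetics transformation model (microbial biomass, dissolved, soil
    and fresh organic matter, and respired carbon dioxide). Also provides a
    coarse pore-network model of overlapping balls whose per-edge diffusional
    conductances can be learned from voxel-scale simulation data by
    normalized stochastic gradient descent, and seeded synthetic
    pore-geometry generators for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
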