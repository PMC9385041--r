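Package: arteriox
Title: Micro-Occlusion and Oxygen Transport Simulation in Cortical Columns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the effect of microsphere occlusions in cerebral
    penetrating arteriole trees on tissue oxygenation. Generates synthetic
    human cortical columns (a penetrating arteriole coupled to a periodic
    capillary bed), solves steady Poiseuille network blood flow with a
    diameter- and haematocrit-dependent viscosity law, computes tissue
    oxygen fields with a Green's function method (vessels as discrete
    oxygen sources, tissue voxels as Michaelis-Menten sinks), enumerates
    single-bead trapping sites and re-solves every occlusion scenario, and
    quantifies the spatial relationship between occlusion sites and hypoxic
    tissue with a pixel-based Gx function and hypoxic-intensity curves.
    The same spatial statistics ingest segmented experimental-style image
    stacks (binary TIFF masks plus bead coordinate tables), so simulated
    and experiment-like data are analysed through one code path.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    data.table,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
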