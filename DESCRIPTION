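Package: latticespectra
Title: Spectral Descriptors and Predictive Surfaces for Molecular Lattice Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for adjacency-spectrum analysis of families of molecular
    lattice graphs, in particular bismuth tri-iodide (BiI3) sheets and
    benzene-ring networks embedded in P-type (schwarzite) surfaces.
    Provides parametric lattice generators indexed by unit-cell counts
    (m, n), spectral descriptors (graph energy, Estrada index, inertia
    indices, nullity, signature, rank), least-squares fitting and
    evaluation of bilinear-quadratic predictive surfaces in (m, n) in the
    QSPR style, and exact-versus-estimated error analysis (MAPE, mean
    absolute error, standard deviation, normal-curve summaries).  Includes
    graph I/O (edge-list TSV, Matrix Market, CSV adjacency) and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite
Config/testthat/edition: 3
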