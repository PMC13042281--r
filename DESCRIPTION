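Package: cellstream
Title: 3D Velocity Vector Fields, Streamline Trajectories and Feature
    Trends for Single-Cell Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Headless analysis of single-cell datasets carrying a
    three-dimensional embedding and projected RNA-velocity vectors.
    Averages per-cell velocities onto a regular 3D grid, integrates
    field lines with Euler or fourth-order Runge-Kutta schemes
    (streamlines, streamlets, cone glyphs), interpolates per-cell
    feature activity onto dense scalar volumes with radial basis
    functions, quantifies feature trends along a trajectory with
    segment means and k-means trend clustering, and expands spherical
    cell selections to clonally related cells in barcoded lineage
    tracing data. Reads h5ad, h5mu and delimited text; includes
    synthetic-fixture generators with analytic vector fields, planted
    feature trends and known clone structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rhdf5,
    stats,
    tools,
    utils
Suggests:
    htmlwidgets,
    optparse,
    plotly,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
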