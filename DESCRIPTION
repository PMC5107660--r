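Package: recell
Title: Agent-Based Simulation and Voronoi Image Analysis of Cell
    Engraftment on Decellularized Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cell engraftment, proliferation and death on a
    three-dimensional decellularized-scaffold lattice under competing
    behavioral rule sets, and quantifies spatial clustering of cells in
    micrograph-like images via bounded Voronoi tessellation and the
    cell-count-corrected variance of tile areas (CVHV). Includes a dual
    -threshold nucleus detector for stained-slice images, synthetic image
    and point-pattern generators with known ground truth, trajectory
    normalization, two-way ANOVA comparison of rule sets, and a parameter
    sensitivity protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    car,
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    deldir,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
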