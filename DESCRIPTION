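Package: watershell
Title: Hydration-Water Structure and Hydrogen-Bond Geometry of Crystalline Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the hydration shell of proteins in the
    crystalline state at controlled hydration levels: construction of
    crystal simulation systems by space-group symmetry expansion, water
    insertion to a target hydration level and counterion neutralisation;
    geometric hydrogen-bond detection with per-water bond-count
    decomposition and ring perception in the water network;
    surface-distance hydration profiles by residue class, distance-angle
    hydrogen-bond geometry maps with peak finding, and hydration-level
    trend curves; an analogous geometry analysis for hydrogen-containing
    crystal structures filtered by experimental method and resolution; and
    synthetic-data generators (ice-rule lattices, water-ring clusters, toy
    protein surfaces, and a rigid three-site water Monte Carlo sampler)
    that stand in for production molecular-dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
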