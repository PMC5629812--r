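Package: landconnect
Title: Landscape Genetic Connectivity via Population Graphs and Circuit Theory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking multi-species gene flow to landscape structure.
    Builds population graphs from codominant microsatellite genotypes, prunes
    edges by edge-exclusion deviance, and computes conditional genetic
    distance and node-based genetic connectivity. Models a resistance raster
    as an electrical lattice to obtain pairwise effective resistance and
    omnidirectional current-density maps with perimeter node placement, plus
    a circular-neighborhood diagnostic relating mean current density to
    effective resistance. Extracts buffered landscape covariates around
    genetic sampling nodes at multiple extents and regresses standardized
    node connectivity on coordinates, sample size and principal components of
    the covariates. Includes a seedable synthetic-data generator (clustered
    three-class cost landscapes and Dirichlet-drift microsatellite genotypes
    whose divergence tracks landscape effective resistance) so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    igraph,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
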