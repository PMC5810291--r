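Package: coalternet
Title: Morphometric Coalteration Network Analysis for Coordinate-Based
    Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds morphometric coalteration ("coatrophy") networks from
    coordinate-based voxel-based-morphometry findings. Implements anatomical
    likelihood estimation (ALE) with Gaussian modeled-alteration maps and
    simulated-null family-wise-error thresholding, atlas-based network node
    construction from ALE peaks, Patel's kappa co-occurrence statistics with
    Dirichlet Monte-Carlo edge significance, and graph-topological
    characterization of the resulting network (node degree, edge betweenness,
    k-core decomposition). Includes a fully synthetic data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'grid.R'
    'core_io.R'
    'ale.R'
    'nodes.R'
    'coalteration.R'
    'network.R'
    'synthdata.R'
    'pipeline.R'
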