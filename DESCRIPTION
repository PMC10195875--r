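Package: annotmix
Title: Assortative Mixing Analysis for Annotated Brain Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how nodal biological annotations mix over the
    edges of weighted brain networks. Implements strength-weighted
    assortativity, rank-based and partial variants, heterophilic mixing
    between pairs of annotations, per-node homophilic ratios and mean
    connection distances, edge-level weighted regression with dominance
    analysis, and multiresolution modularity communities with consensus
    clustering. Inference is standardized against spatial-autocorrelation
    preserving surrogate annotations (spherical rotations, Moran spectral
    randomization, variogram-matched surrogates) with two-sided permutation
    tests and Benjamini-Yekutieli false-discovery-rate control. A synthetic
    generator produces spatially embedded networks with distance-decaying
    connectivity, spatially autocorrelated annotation fields and planted
    (dis)assortative wiring, so the whole pipeline can be exercised without
    any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
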