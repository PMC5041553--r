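Package: esaprot
Title: Elastic Shape Analysis of Protein Backbone Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pairwise comparison of protein three-dimensional structures by
    elastic shape analysis. Backbone geometry (full backbone, C-alpha trace,
    or per-residue backbone centroid) is augmented with residue-level
    auxiliary channels (backbone dihedral angles, hydrophobicity, polarity,
    residue mass, functional-group class, side-chain atom count) to form a
    composite open curve, which is transformed to its square-root velocity
    function, optimally rotated by singular value decomposition and
    optimally reparameterized by dynamic programming; dissimilarity is the
    geodesic distance on the unit sphere of normalized square-root velocity
    functions. Includes all-vs-all distance matrices, sigmoid similarity
    conversion, clustering-based evaluation (k-means, fuzzy c-means,
    spectral k-means) with Rand index, precision, recall and F-measure, and
    a deterministic synthetic backbone generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
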