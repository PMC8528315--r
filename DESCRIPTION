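Package: vesselvec
Title: Segmentation-Free Vectorization of Vascular Networks from 3-D Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extracts vectorized blood-vessel networks (vertices, centerline
    edges, strands and bifurcations) directly from unsegmented 3-D
    fluorescence microscopy volumes. Vessels are enhanced by a bank of
    multi-scale Laplacian-of-Gaussian matched filters applied in the Fourier
    domain; seed vertices are energy minima, and centerlines are traced by a
    watershed-style minimum-energy exploration between vertices. Includes
    anatomical network statistics via a consecutive-cylinder idealization, a
    two-photon microscopy image simulator with a Poisson-surrogate noise
    model, phantom vascular network generation, and an evaluation framework
    (ROC sweeps of vector energy thresholds against ground-truth masks).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    png,
    jsonlite,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
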