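Package: profnet
Title: Sample-Characteristic-Specific Gene Regulatory Networks with
    Sparse Common Components and Edge-Knockout Importance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers per-sample gene regulatory networks from expression
    data with a kernel-weighted L1-penalized varying-coefficient
    regression, in which the strength of each regulator-target edge
    varies with a per-sample modulator such as drug sensitivity.
    Constant-bandwidth, adaptive k-nearest-neighbour and multivariate
    Gaussian kernels are provided.  The resulting stack of networks is
    summarised by network-constrained sparse common component analysis
    (sparse loadings smoothed over a Jaccard gene-similarity graph) and
    interrogated by an edge-knockout importance procedure that ranks
    regulator-target interactions by the significance of the drop in
    cross-validated prediction accuracy when the edge's features are
    removed.  Seeded generators with known ground truth support
    end-to-end recovery benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    e1071,
    ranger,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
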