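Package: cytogravity
Title: Simulated-Microgravity Immune Profiling with Synthetic Mass Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-cell mass-cytometry (CyTOF) studies of immune
    adaptation to simulated microgravity. Generates fully specified synthetic
    CyTOF experiments with ground-truth effects and palladium combinatorial
    barcoding, gates events into 18 immune subsets through a deterministic
    threshold-rule hierarchy, derives arcsinh-median stimulation-response
    features (252 in the default design), fits an elastic-net model by
    coordinate descent with leave-one-donor-out cross-validated penalty
    selection and exact paired Wilcoxon model significance, screens features
    with the Benjamini-Krieger-Yekutieli two-stage FDR procedure, and builds
    Bonferroni-thresholded Spearman correlation networks with modularity
    communities and a t-SNE layout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    Rcpp,
    utils,
    igraph,
    jsonlite,
    yaml,
    Rtsne
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
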