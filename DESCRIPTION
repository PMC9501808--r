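Package: paramotion
Title: Interdomain Motion from Paramagnetic NMR Restraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies rigid-body interdomain motion in multidomain proteins
    from paramagnetic NMR data. Fits anisotropic magnetic susceptibility
    (delta-chi) tensors of bound lanthanides to pseudocontact shifts (PCS),
    residual dipolar couplings (RDC) and residual chemical shift anisotropy
    (RCSA) measured in the metal-carrying domain, including iterative group
    weighting, lanthanide-position refinement and bootstrap uncertainties.
    Predicts restraints for rigid-body arrangements of a second domain
    expressed as homogeneous transforms, and selects a minimal conformational
    ensemble (members, non-negative populations and effective size) with a
    genetic algorithm whose fitness embeds the Bayesian information
    criterion, populations being assigned by sum-constrained non-negative
    least squares. A seeded synthetic-data generator provides ground-truth
    scenarios for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
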