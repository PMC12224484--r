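Package: connridge
Title: Connectome-Based Classification of Depression Phenotypes with Logistic Ridge Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for case-control classification of overlapping depression
    phenotypes from brain connectomes. Provides a synthetic cohort generator
    with covariance-structured functional and structural connectomes, sex-exact
    nearest-neighbour case-control matching on age and intracranial volume,
    childhood-trauma score thresholding of cases, edge-feature construction
    (upper-triangle vectorization, group proportional thresholding, modality
    stacking, train-set z-normalization), pair-level nested 6x5 cross-validated
    logistic ridge regression, coefficient-stability feature selection with
    Jaccard set comparison, and hypergeometric enrichment of selected edges
    over a subnetwork partition with Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
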