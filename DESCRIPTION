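Package: ocplsda
Title: Orthogonally Constrained PLS Discriminant Analysis for LC-MS Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discriminates two clinical groups from untargeted LC-MS
    feature-intensity tables while excluding the influence of metadata
    covariates. Implements PLS2 discriminant analysis with orthogonal score
    constraints (oCPLS2-DA), post-transformation into predictive and
    Y-orthogonal components, N-fold full cross-validation with Q2 and
    permutation testing, cross-validated ROC analysis, Monte-Carlo stability
    selection of marker features, a univariate t-test/FDR complement, and
    putative metabolite annotation by adduct mass matching. Includes a
    synthetic-data generator emulating small two-group amniotic-fluid study
    designs with known markers and confounded features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    pROC
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
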