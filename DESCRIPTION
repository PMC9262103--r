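Package: ddrcca
Title: Domain-Driven Dimension Reduction and Canonical Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements domain-driven dimension reduction (DDR): principal
    component analysis applied separately within functionally defined variable
    sub-domains, with the dimensionality of each sub-domain chosen
    automatically by a two-way (subject-wise and variable-wise) cross-validated
    PRESS criterion, followed by varimax rotation of the principal loadings.
    The concatenated rotated components of two data blocks (for example
    behavioural subject measures and functional-connectivity brain measures)
    are related by canonical correlation analysis with max-statistic
    permutation significance testing, canonical-loading interpretation, and a
    family-respecting k-fold cross-validated stability analysis. Includes
    preprocessing utilities (quality control, rank-based inverse-normal
    transformation, de-confounding, benchmark-based sign alignment),
    connectivity-matrix helpers (Tikhonov-regularised partial correlation,
    region sub-domain construction, signed canonical strength maps), and a
    fully seeded synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
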