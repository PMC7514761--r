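Package: auxselect
Title: Information Criteria for Auxiliary Variable Selection in
    Incomplete Data Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding whether auxiliary variables improve the
    predictive distribution of primary variables when part of the primary
    vector is latent.  Implements a family of generalized Akaike-type
    information criteria built from empirical sandwich information
    matrices, a latent-variable leave-one-out cross-validation risk
    estimator asymptotically equivalent to the criterion, maximum
    likelihood estimation of a two-component Gaussian mixture candidate
    model (with and without one auxiliary variable) by EM, and the
    Monte-Carlo machinery to evaluate true Kullback-Leibler risk of the
    resulting plug-in predictive distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
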