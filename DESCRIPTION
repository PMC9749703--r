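Package: pspaf
Title: Pathway-Specific Population Attributable Fractions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of pathway-specific population attributable fractions
    (PS-PAFs) for binary exposures acting on a binary disease outcome through one
    or more mediators, alongside the total, direct and indirect attributable
    fractions they are compared against. Supports cohort, cross-sectional and
    frequency-matched case-control designs (controls reweighted from a known
    disease prevalence), plug-in estimation through weighted logistic outcome
    models and per-mediator regression models, bootstrap standard errors and
    confidence intervals, and a structural-equation simulator whose exact
    enumeration oracle supplies ground-truth counterfactual functionals for
    finite-support models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
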