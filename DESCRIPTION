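Package: twinprop
Title: Maternal-Age-Specific Twinning Propensity and Projection of Future
    Twin Births
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates maternal-age-specific twinning probabilities and
    country baseline twinning rates from retrospective birth histories
    using a linear probability model with country fixed effects, and
    propagates the estimates (with posterior uncertainty) onto projected
    maternal age structures and birth counts to estimate future twinning
    rates and twin-birth counts.  Includes a synthetic birth-history and
    population-projection generator with known ground truth, a country
    by period panel regression of period twinning rates on mean maternal
    age at birth, scenario projection with per-draw uncertainty
    propagation, and a counterfactual decomposition of the sources of
    change in rates and counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    MASS,
    metafor,
    sandwich,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
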