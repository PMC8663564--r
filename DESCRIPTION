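Package: practicecurve
Title: Learning Curves and Practice Effects in High-Frequency Repeated Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies short-term learning and long-term practice effects in
    irregular, user-scheduled repeated-testing data such as smartphone-based
    functional tests for multiple sclerosis. Provides readers and validators
    for long-format test-record tables, a synthetic cohort generator with
    known ground truth, study-style inclusion filters and cohort
    characteristics, first/fifth/last summary comparisons with confidence
    intervals, linear quantile regression over the first five trials with a
    slope-equality test, and a four-model learning-curve analysis (linear and
    quadratic mixed models, a penalized regression spline, and a bounded
    growth nonlinear mixed model) compared by conditional RMSE and (effective)
    degrees of freedom, with derived practice metrics such as 50% and 90%
    practice points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    minpack.lm,
    mgcv,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
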