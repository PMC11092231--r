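Package: mesascale
Title: Meal and Snack Assessment Quality Scale via Unfolding Item Response Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs and applies a meal-quality scale for schoolchildren's
    dietary recalls. Foods reported at six daily eating occasions are mapped to
    NOVA processing classes (unprocessed/minimally processed, processed,
    ultra-processed) and turned into binary consumption items; item parameters
    of a dichotomous generalized graded unfolding model (GGUM) are estimated by
    marginal maximum likelihood with an EM algorithm; respondents are scored by
    expected a posteriori estimation, placed on a mean-100/SD-10 reporting
    scale and classified into healthy, mixed and unhealthy meal-quality levels.
    Includes dimensionality checks via tetrachoric correlations and
    minimum-residual factor analysis, an item-retention filter, likelihood-ratio
    tests of differential item functioning with anchor purification, test
    information and standard-error curves, survey-weighted level prevalence
    with stratified cluster-bootstrap confidence intervals, and a synthetic-data
    generator that emulates the study design end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
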