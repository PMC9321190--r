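Package: neglectweights
Title: Endpoint-Weighting Analysis of Line Bisection and Endpoint Reproduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying spatial neglect from line bisection and
    endpoint reproduction trials using the endpoint-weightings model. A
    bisection response is modelled as an affine function of the left and right
    endpoint positions; the endpoint weightings bias (EWB, right minus left
    weighting) and its reproduction-task analogue (EWBr) are estimated per
    participant by ordinary least squares, including the length-slope route
    (EWB equals twice the slope of directional bisection error on line length)
    for designs that vary length only. Includes a generative simulator of
    bisection and reproduction behaviour for cohorts of control and neglect
    agents, Crawford-Howell modified-t single-case comparisons with
    control-derived cut-offs, small-sample standardized group effect sizes for
    unequal variances with Welch degrees of freedom, and an end-to-end pipeline
    producing participant reports, group summary tables and the EWB-EWBr
    association.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
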