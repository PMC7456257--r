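Package: crownprofile
Title: Outermost Crown Profile Modelling for Conifer Saplings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the outermost crown profile of naturally regenerated
    conifer saplings by nonlinear quantile regression of power-exponential
    and variable-exponent (Kozak-type) crown radius equations over a grid of
    quantiles, selects the quantile that best matches a polynomial frontier
    (boundary) estimate of each sapling's branch-tip cloud, and derives
    crown-morphology comparisons between silvicultural treatments: depth of
    the largest crown radius, largest crown radius, upper-crown volume by
    rotational integral, and annual branch-length growth. Includes a
    synthetic stand generator with one-sided below-envelope noise so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    quantreg,
    optparse
Config/testthat/edition: 3
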