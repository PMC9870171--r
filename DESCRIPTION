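Package: codendsel
Title: Size Selectivity of Trawl Codends from Covered-Codend Catch Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood estimation of trawl codend size selectivity
    from covered-codend catch-at-length data. Fits the classical Logit,
    Probit, Gompertz and Richards retention curves and their
    contact-probability mixture variants to haul-pooled binomial catch data
    with compartment subsampling, selects among families by AIC, and tests
    fit quality by deviance against a chi-square reference. Uncertainty is
    quantified by a double bootstrap (hauls resampled between, fish within)
    with Efron percentile confidence intervals, and gears are compared with
    paired delta selectivity curves. Also characterises codend motion from
    1-Hz depth and accelerometer records (total acceleration, peak-to-peak
    amplitude ratio, oscillation period, stable-depth segmentation) and
    ships synthetic-data generators with known ground truth for every
    pipeline stage.
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
    jsonlite,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
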