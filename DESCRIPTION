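Package: vfcensor
Title: Censoring-Based Comparison of Size III and Size V Automated Perimetry
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Makes standard automated perimetry 24-2 visual fields acquired
    with Goldmann stimulus size III and size V directly comparable. Raw
    decibel sensitivities are censored at stimulus-specific thresholds
    (values below the threshold are replaced by it), converted to
    age-corrected total deviations against a normative model, and compared
    pointwise. An exhaustive grid search selects the censoring-threshold
    pair whose mean censored-pair total-deviation difference is closest to
    zero, and an agreement battery (subgroup means, paired t-test, ordinary
    least squares against the line of unity, Bland-Altman limits of
    agreement) quantifies how well the two stimulus sizes agree. A seeded
    generator simulates paired glaucoma and NAION cohorts with
    floor-dominated sub-threshold noise for validation work.
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
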