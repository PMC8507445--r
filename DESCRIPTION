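Package: larisk
Title: Lifetime Attributable Risk Projection for Nuclear-Medicine Exposures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Projects the lifetime attributable risk (LAR) of
    radiation-induced cancer incidence and mortality after diagnostic
    nuclear-medicine examinations, by integrating survival-weighted
    site-specific excess cancer rates of the BEIR VII / EPA family over
    attained age. Supports patient cohorts with reduced life expectancy
    through a k-year-survival-derived annual survival probability applied
    to the population life table, age-interpolated organ dose coefficients
    with the bone-seeker convention, and equal-risk optimization of
    administered activity and acquisition time around a fixed
    image-quality (counts) budget. Ships a seeded synthetic-data generator
    for life tables, baseline cancer rates, dose coefficients and risk
    model parameters so the whole pipeline is testable without national
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
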