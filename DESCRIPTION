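Package: nutrifu
Title: Nutrition-Based Functional Units for Livestock Carbon Footprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-expresses livestock greenhouse-gas emission intensities under
    nutrition-based functional units. Provides a liveweight -> carcass ->
    edible-meat conversion chain driven by kill-out and meat-yield
    coefficients, carbon footprints per gram of omega-3 or EPA+DHA, and a
    configurable nutrient-index engine (the UKNI family of percent-of-daily-
    intake scores with optional penalty nutrients) yielding footprints per 1
    percent of recommended daily intake. Ships the seven UK beef, lamb,
    chicken and pork study systems as plain-text fixtures, a synthetic study
    generator for property testing, and a command-line interface for scoring,
    ranking and plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
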