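Package: freehb
Title: Plasma Free Hemoglobin Measurement, Method Comparison, and
    Interference-Aware Reporting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying plasma free hemoglobin (fHb) by Harboe
    spectrophotometry, estimating fHb and total bilirubin from analyzer
    serum indices (hemolysis/icterus/lipemia), comparing the two measurement
    routes with Passing-Bablok regression, Bland-Altman agreement and
    Spearman rank correlation, locating the bilirubin concentration above
    which icteric interference compromises agreement, and applying a
    configurable rule-based engine that decides whether and how an fHb
    result is reported in the presence of hemolysis, icterus and lipemia
    interference. Includes a synthetic ECMO-cohort generator so every
    analysis is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
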