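Package: benfaudit
Title: Benford's Law Auditing of Species Occurrence Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens long-format species monitoring tables for compliance of
    abundance first digits with Benford's law, classifies per-species
    compliance with an interquartile-range threshold of compliance, and
    determines the minimum number of occurrence sites required before species
    distribution modelling by maximising the true skill statistic over
    candidate site thresholds. Ships a synthetic monitoring-data generator
    with controlled digit behaviour and planted occurrence-site thresholds so
    the whole workflow can be validated without access to a national
    monitoring database, plus a small command-line front end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
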