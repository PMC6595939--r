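Package: chronojet
Title: Chronotype and Social Jetlag Estimation from Wearable Sleep Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating chronotype and social jetlag from
    longitudinal wearable-device sleep records. Computes per-night mid-sleep
    points on a noon-anchored night axis, per-subject mid-sleep aggregates on
    work and free nights, the sleep-debt-corrected mid-sleep on free days
    (MSFsc), signed social jetlag (SJL), chronotype and nap-group
    classifications, and cohort-level summaries (distributions, correlations,
    two-sample tests, regressions, and cross-validated random-forest feature
    importance). Includes a synthetic-cohort generator with known ground
    truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
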