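Package: evidemcda
Title: Linear Additive MCDA Value Appraisal with the EVIDEM Core Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hospital-based health technology assessment by
    multi-criteria decision analysis (MCDA) under the EVIDEM framework: a
    validated 13-criterion quantitative core model and 7-criterion qualitative
    contextual tool, panelist-level weight and score elicitation matrices with
    range validation and aggregation, normalized-weight/standardized-score
    linear additive value estimation with explicit missing-criterion policies,
    intervention ranking, Monte-Carlo rank-stability analysis, and a synthetic
    panel generator for end-to-end testing. Ships an aggregated appraisal of
    five DPP-4 inhibitors by a six-member hospital committee as a worked
    example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
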