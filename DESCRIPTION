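Package: codeshift
Title: Stability of Administrative-Claims Surveillance Trends Under Coding Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how sensitive chronic-disease surveillance
    estimates from coded administrative health data are to changes in the
    coding process. Generates synthetic person registries and diagnosis
    claims with known ground truth (including ICD-version era switches and
    injectable coding disruptions), applies parametric case-definition
    algorithms to produce incident and prevalent counts by year, age group
    and sex, models trends with negative binomial regression and Poisson
    estimating equations with AR(1) working correlation (restricted cubic
    spline year effects), builds observed-expected control charts with
    limits at the model prediction plus or minus k pooled standard
    deviations, and compares out-of-control classifications across
    algorithms with McNemar tests under Holm-Bonferroni adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    MASS,
    data.table,
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
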