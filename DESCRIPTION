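Package: amiepisodes
Title: Episode-of-Care Construction from Hospitalization Claims for
    Acute Myocardial Infarction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds discrete admission episodes of acute myocardial
    infarction (AMI) from administrative hospitalization claims.
    Implements an ICD-10 case definition (I21.X as primary or secondary
    diagnosis, excluding I22-I25), a three-condition date-window
    algorithm that merges adjacent claims arising from monthly billing
    splits, inter-hospital transfers and early readmissions into
    episodes of care, episode-level attribution of emergency-department
    route and invasive coronary procedures, and stratified tabulation of
    proportions with binomial confidence intervals. A synthetic claims
    generator with planted ground-truth episodes makes every stage
    testable without access to real claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
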