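Package: cadbreakeven
Title: Break-Even Pricing Analysis for Deep-Learning CAD in CT Lung
    Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate when deep-learning computer-aided
    detection (DL-CAD) software for lung nodules becomes cost-saving in a
    CT lung cancer screening programme. Pools published radiologist
    reading times with and without CAD using a random-effects model
    (DerSimonian-Laird or unweighted), derives pre-screening-reader time
    savings from nodule prevalence and a rule-out assumption, and
    computes break-even per-case prices and minimum workloads under
    pay-per-use, one-off license, and yearly-subscription pricing in
    several salary settings. Ships the published reading-time evidence
    table as a fixture, a simulator of multi-study reader-timing corpora
    with known ground truth, and reporting helpers that reproduce the
    published result tables and figure conventions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
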