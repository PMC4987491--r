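Package: qhws
Title: Quality Assessment of Health Websites Against Healthy People 2020 Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for scoring health-related websites against the Healthy
    People 2020 website-quality objectives HC/HIT-8.1 (disclosure-based
    information reliability) and HC/HIT-8.2 (usability). Provides the survey
    instrument as configurable data (6 reliability criteria with required,
    optional, page-scoped and conditional disclosure elements; 19 usability
    principles with 59 task-based measures rated 1-4), sample-eligibility
    filtering, rubric aggregation to per-site scorecards, interrater
    reliability statistics (Cohen's kappa, two-way intraclass correlation)
    with Altman benchmark categorisation and training-gate logic, binomial
    compliance estimation with Wald standard errors and confidence intervals,
    minimal-statistical-significance target setting, and a seeded synthetic
    assessment generator for end-to-end testing when raw review data are
    unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
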