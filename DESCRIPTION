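Package: trialinform
Title: Rule-Based Classification of Randomized Trial Informativeness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies registered randomized clinical trials by four sequential
    conditions of informativeness (feasibility, reporting, importance, design)
    from structured registry records modeled on ClinicalTrials.gov fields.
    Provides cohort eligibility screening, a sequential gating pipeline with
    funnel summaries, exact Clopper-Pearson binomial intervals, 2xK Fisher exact
    tests by enumeration, Yates-corrected chi-square tests, Cohen's kappa, a
    margin-constrained synthetic cohort for reproducing published summary
    statistics, and a parametric random-registry generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
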