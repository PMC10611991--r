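Package: misoqba
Title: Cohort Endpoints, Exact Inference, and Quantitative Bias Analysis for
    Self-Managed Medication Abortion Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for prospective cohort studies of self-managed
    medication abortion with misoprostol alone. Derives effectiveness and
    safety endpoints from self-reported follow-up data (including a
    last-recorded-follow-up carry-forward rule), tabulates stratified
    frequencies with Wilson score or Clopper-Pearson confidence intervals,
    runs chi-square and Fisher exact contingency-table tests, and performs a
    Monte Carlo quantitative bias analysis correcting the crude effectiveness
    proportion for self-report outcome misclassification and for selection
    from outcome-dependent loss to follow-up. A seeded synthetic-cohort
    generator with a separate truth record supports testing every stage
    without access to legally sensitive individual-level data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
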