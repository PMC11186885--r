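Package: tdpengine
Title: TDP-43 Neuropathology Classification and Multicenter Cohort Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with coded multicenter autopsy registry data on
    TDP-43 proteinopathy. Provides a rule-based classifier that assigns each
    autopsied participant a TDP-43 category (No TDP-43, LATE-NC, ALS/FTLD-TDP,
    or Other TDP-43) with LATE-NC stage and ALS/FTLD subtype; availability and
    missingness profiling for regional TDP-43, FTLD-TDP, motor-neuron-inclusion
    and hippocampal-sclerosis assessments; association analyses (rank-sum and
    chi-square group comparisons, adjusted and multilevel logistic regressions
    with post-hoc category contrasts); and a seeded generator of synthetic
    multicenter cohorts with configurable prevalences, effect sizes, and
    structured missingness mechanisms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    emmeans,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
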