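Package: ckdscreen
Title: Individual-Based Microsimulation of Albuminuria Screening for
    Chronic Kidney Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An annual-cycle, individual-based microsimulation of chronic
    kidney disease (CKD) progression in an adult population, built to compare
    urinary albumin-creatinine screening strategies in a cost-effectiveness
    framework. The model synthesises a cohort with age, sex, body mass index
    and systolic blood pressure drawn from LMS (lambda-mu-sigma) growth
    references, simulates diabetes, albuminuria onset and progression,
    glomerular filtration rate (GFR) decline, renal replacement therapy and
    mortality, applies a two-repeat screening test cascade with
    ACE-inhibitor therapy, and aggregates QALYs and costs (discounted and
    undiscounted) into scenario comparisons with confidence intervals.
    Includes calibration hooks, a one-way sensitivity sweep, and a validation
    report comparing simulated marginals to the input tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
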