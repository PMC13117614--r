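Package: lcscea
Title: Cost-Effectiveness Model of One-Off Low-Dose CT Lung Cancer
    Screening in an Asbestos-Exposed Smoking Population
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree plus Markov cohort state-transition model comparing
    a single round of low-dose computed tomography (LDCT) lung cancer
    screening against passive surveillance in a population aged 55-80 with
    former asbestos exposure and at least 10 pack-years of smoking. The
    cohort, stratified by sex and age group, moves through 3-month cycles over
    a lifetime horizon across undiagnosed and diagnosed cancer stages with
    years-since-diagnosis tunnel states. Includes iterative calibration of
    stage-specific diagnosis probabilities to an observed stage distribution
    at diagnosis, half-cycle corrected discounted life years, QALYs and costs,
    incremental cost-effectiveness ratios, overdiagnosis and false-positive
    surgery counts, probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, and declarative scenario analyses. All default
    parameters are synthetic stand-ins calibrated to published aggregate
    values; ggplot2 plotting and broom-style tidiers are provided.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
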