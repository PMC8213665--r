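Package: qreportr
Title: Quantitative Brain-Volumetry Reports and Multi-Rater Study Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for normative modelling of regional brain volumes and for
    evaluating quantitative volumetric reports in multi-rater clinical
    accuracy studies. Fits per-region normative models (volume regressed on
    age, sex and total intracranial volume) on a healthy reference
    population and converts single-subject volumes into percentiles;
    computes brain parenchymal fraction and scan-quality metrics; renders a
    single-page quantitative report with a log-scale, traffic-light
    coloured rose plot. A companion analysis framework computes
    signal-detection metrics (sensitivity, specificity, accuracy), McNemar
    and paired t tests with Cohen's d, Cohen's kappa against a gold
    standard, Cronbach's alpha and intraclass correlation coefficients, a
    four-way mixed ANOVA of assessment confidence, and paired-design
    sample-size estimates. Synthetic generators for normative cohorts,
    dementia test cohorts with regional atrophy, randomised rating
    schedules and simulated raters make the whole pipeline testable
    without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
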