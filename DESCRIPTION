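Package: creatref
Title: Indirect Pediatric Serum Creatinine Reference Intervals from
    Hospital Laboratory Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates age- and sex-specific 95% reference intervals for
    serum creatinine in children (1 month to 18 years) from routinely
    collected hospital laboratory data, using indirect sampling: individuals
    with repeated measurements are excluded as likely renal follow-up
    patients, a one-sided Tukey upper fence (Q3 + 1.5 IQR) trims residual
    pathological values per stratum, and parametric limits (mean +/- 1.96 SD)
    are computed in 36 age/sex groups. Includes a synthetic electronic health
    record cohort generator with known truth for validating every pipeline
    stage, enrollment flow accounting, upper-reference-limit monotonicity
    (reversion) checks, adolescent sex-difference summaries, and a
    diagnosis-flag sensitivity comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
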