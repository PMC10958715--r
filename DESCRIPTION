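Package: faersignal
Title: Disproportionality Signal Detection for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for spontaneous adverse-event
    reports in the public FAERS quarterly ASCII dialect. Reads the six
    quarterly tables (DEMO, DRUG, REAC, OUTC, THER, INDI), deduplicates
    case versions, isolates a target drug as primary suspect via a synonym
    dictionary, builds drug-event 2x2 contingency tables at the MedDRA
    preferred-term and system-organ-class levels, and computes the four
    classical disproportionality statistics (reporting odds ratio,
    proportional reporting ratio with chi-squared, the Bayesian confidence
    propagation neural network information component, and the empirical
    Bayes geometric mean) with 95 percent intervals and combined signal
    criteria. Also summarizes cohort demographics, serious outcomes and
    indications, and time to onset from first therapy start. A synthetic
    report generator with planted drug-event signals makes the whole
    pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
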