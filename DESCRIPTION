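Package: drgcost
Title: Hospitalization Expense Structure and Determinants Under DRG Payment Reform
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for front-page inpatient billing records of
    heart-failure admissions across diagnosis-related-group (DRG) payment
    reform phases: record validation, coding and inclusion filtering, consumer
    price index (CPI) standardization of expenses, rank-based univariate
    screening, dummy-coded linear regression of log expenses, structural
    variation statistics (VSV, DSV, CRSV) of itemized expense shares, and a
    gray relational analysis of itemized expenses against per-admission
    totals. A synthetic cohort generator with a known log-linear cost model
    supports end-to-end testing and parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
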