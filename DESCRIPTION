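Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance pipeline for FAERS-style
    spontaneous adverse event report data: parsing of the quarterly
    '$'-delimited ASCII tables, case deduplication by the CASEID/FDA_DT/
    PRIMARYID rule, drug name standardization via a synonym dictionary,
    construction of drug-event 2x2 contingency tables at the MedDRA
    preferred-term and system-organ-class levels, four-algorithm
    disproportionality analysis (reporting odds ratio, proportional
    reporting ratio with chi-squared, the BCPNN information component, and
    the empirical-Bayes gamma-Poisson shrinker EBGM/EB05), sex-stratified
    subgroup analysis, and Weibull time-to-onset modelling. Includes a
    synthetic FAERS-like data generator with planted ground truth so the
    whole pipeline is testable without access to the live database, plus a
    utility that reconstructs 2x2 tables from published (ROR, CI,
    chi-squared) triples for cross-checking reported signal tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    fitdistrplus,
    jsonlite
Config/testthat/edition: 3
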