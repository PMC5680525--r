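Package: querysignal
Title: Pharmacovigilance Signal Detection from Search Query Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects adverse-reaction signals associated with a target substance
    from anonymized search query logs. Queries are mapped to substance and
    symptom concepts with a synonym lexicon, media-driven query texts are
    filtered out, each user's timeline is anchored at the date of their first
    substance query ("day 0"), and four disproportionality measures (QR, QLRS,
    QPRR, PQR) are computed from per-symptom 2x2 contingency tables. Signals
    are validated against an aggregated spontaneous-report reference set via
    ROC analysis and rank correlation with greedy outlier exclusion.
    Geographic usage prevalence is estimated from per-unit term-query
    fractions with a stepwise linear model that transfers across aggregation
    levels, and symptom onset is profiled as a lag-aligned query fraction
    relative to day 0. A synthetic query-log generator with planted ground
    truth supports end-to-end recovery testing.
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
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
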