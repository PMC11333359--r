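Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("pvsignal", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: End-to-end pharmacovigilance disproportionality analysis for
    FAERS-style quarterly report tables: case deduplication, primary-suspect
    drug filtering, per-(drug, event) 2x2 contingency construction, four
    signal-detection statistics (reporting odds ratio, proportional reporting
    ratio with chi-square, BCPNN information component, and a simplified
    empirical Bayes geometric mean) with their positivity criteria, MedDRA
    preferred-term to system-organ-class rollup, demographic and signal
    reporting surfaces, and a synthetic report generator with planted
    drug-event associations for validation without access to the real
    database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
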