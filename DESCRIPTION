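Package: survspot
Title: Survival Screening of Somatic Mutation Hotspots with an Exact
    Log-Rank Null
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@survspot.org",
           role = c("aut", "cre"))
Description: Detects recurrently mutated amino-acid positions (hotspots)
    in somatic mutation tables and screens them for association with
    overall survival. Because hotspot carriers are few compared to the
    rest of a cohort, the classical chi-squared approximation of the
    log-rank test is unreliable; survspot tabulates the null
    distribution of the signed log-rank statistic conditional on the
    observed times and censoring, by exhaustive enumeration of group
    assignments when feasible and otherwise by sampling stratified on
    the number of events in the carrier group, and reports two-sided
    empirical p-values alongside the classical log-rank and Cox
    proportional-hazards statistics. Includes tumor-mutation-burden
    based hypermutation filtering, four carrier-versus-comparison
    screening strategies, and a synthetic cohort generator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
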