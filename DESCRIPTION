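Package: phenoprev
Title: Computable Phenotyping and Prevalence Estimation from Administrative Claims
Version: 0.1.0
Authors@R:
    person("Open", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Identifies prevalent lung-cancer patients in administrative
    claims databases with a configurable grid of rule-based algorithms
    (distinct ICD-10-coded months in an index year, with or without an
    oncological-procedure lookback), estimates stratified prevalence rates
    per 100,000 with nonparametric bootstrap confidence intervals, and
    selects the algorithms most consistent with external aggregated
    benchmarks. Ships a synthetic claims-data generator with known ground
    truth so the full pipeline is testable without access to restricted
    national databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
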