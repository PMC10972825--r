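Package: craburden
Title: Comparative Risk Assessment of Risk-Attributable Disease Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the comparative risk assessment (CRA) framework used
    to quantify disease burden attributable to modifiable risk factors:
    method-of-moments exposure distributions, relative-risk curves with
    theoretical minimum-risk exposure levels (TMRELs), population attributable
    fractions (PAFs) for continuous and categorical exposures and their
    multiplicative combination, attributable DALYs with draw-level 95%
    uncertainty intervals, direct age-standardization, trend arithmetic, and
    sociodemographic-index (SDI) quintile and correlation analysis. Ships a
    synthetic-world generator with known ground-truth PAFs so the whole
    pipeline is testable end to end, plus the published global GBD 2019
    cancer trend table as a plain-text fixture.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    stats,
    utils,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
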