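Package: screenlexis
Title: Lexis-Grid Evaluation of Phased Cancer-Screening Rollouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quasi-experimental evaluation of staggered mammography-screening
    programmes from cancer-registry incidence files.  Implements
    incidence-based breast-cancer mortality contrasts between regions on an
    age-by-calendar-year (Lexis) grid: Mantel-Haenszel stratified rate ratios
    with Breslow-Day person-time variances, a double-difference (ratio of
    rate ratios) net-effect estimator with Woolf-like confidence intervals,
    deaths-averted and participation-deattenuated efficacy conversions,
    Poisson band trends in stage 2-4 incidence, and a conditional-Poisson
    (within-cell binomial split) model of the time-varying net stage 2-4
    deficit.  A mechanistic registry microsimulation with biennial
    invitations, stage shift and lead time allows every analysis step to be
    validated without access to confidential registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
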