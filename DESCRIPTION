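Package: countydid
Title: Difference-in-Differences Estimation for County-Year Rate Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quasi-experimental evaluation of county-level policy
    adoption on demographic rates, motivated by staggered federal funding
    programs and teen birth rates. Provides a synthetic county-year panel
    generator with known ground truth, construction of analysis-ready panels
    (age-specific or pooled birth rates per 1,000, log(1+R) outcomes, lagged
    treatment and covariates, sparse-covariate interpolation, sample
    exclusion filters), two-way fixed-effects regression with county and
    state-year fixed effects, optional county-specific linear trends and
    county-clustered standard errors, and a group-time average treatment
    effect estimator for staggered adoption with unconditional and doubly
    robust conditional variants, event-study and overall aggregation,
    multiplier-bootstrap simultaneous bands, and a pre-trend Wald test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    yaml
Config/testthat/edition: 3
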