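Package: penslife
Title: Mortality Inequality and Period Life Tables for Retirement Pensioners by Pension Income
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the socioeconomic mortality gradient among
    retirement pensioners from individual administrative records. Provides a
    synthetic record generator with income-group-dependent Gompertz-Makeham
    mortality, an auditable exclusion cascade and pension-income classifier,
    person-years exposure and death tabulation by single year of age,
    penalized B-spline (P-spline) Poisson graduation of death rates with a
    discrete beta-kernel cross-check, complete period life tables for ages
    65 to 101 with Chiang-style variances and one-tailed tests of
    life-expectancy differences, and relative-mortality / mortality-improvement
    inequality summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
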