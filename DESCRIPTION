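Package: mrkit
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) analysis from
    GWAS summary statistics: reading and harmonizing exposure and outcome
    association tables to a shared effect allele, selecting independent
    genome-wide-significant instruments with an F-statistic screen and greedy
    LD clumping, and estimating the causal effect with the inverse-variance
    weighted (IVW) method, MR-Egger regression, and the weighted median
    estimator with a parametric-bootstrap standard error. A sensitivity
    battery provides Cochran's Q and I-squared heterogeneity statistics, the
    Egger-intercept pleiotropy test, leave-one-out analysis, and plot-ready
    forest, scatter and funnel diagnostics. A simulation module generates
    two-sample summary statistics with known ground truth, configurable
    directional or balanced pleiotropy and an InSIDE toggle, for
    parameter-recovery and type-I-error experiments. Ships a seven-variant
    aspirin-use / allergic-rhinitis instrument set as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
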