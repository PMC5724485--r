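Package: trajarea
Title: Area-Between-Curves Analysis of Longitudinal Randomised Trials
Version: 0.1.0
Authors@R: person("trajarea", "authors", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint maximum-likelihood estimation of occasion-specific
    treatment-effect regressions on correlated repeated measures with
    incomplete outcome records (seemingly unrelated regressions by
    full-information maximum likelihood), standardisation of per-occasion
    effects to Cohen's d across changing instruments, combination into an
    area-between-curves summary with a Wald test and participant-resampling
    bootstrap confidence intervals, plus exact 2xK contingency tests,
    proportional-odds ordinal regression and intraclass correlations for
    coder reliability. Includes a calibrated synthetic two-arm trial
    generator so the whole pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
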