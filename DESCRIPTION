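Package: doseCalib
Title: Inverse Regression Dose Estimation for Cytogenetic Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood fitting of Poisson and two-parameter compound
    Poisson (Hermite, Neyman type A, negative binomial) dose-response
    calibration curves for chromosome aberration counts, and Bayesian-type
    calibrative densities of the absorbed radiation dose for new count
    samples. Provides u-test dispersion diagnostics, delta-method mean priors
    with normal and gamma variants and their validity bounds, closed-form
    predictive distributions through Hermite and negative binomial laws,
    Panjer and compound-Hermite recursions for overdispersed responses, a
    complete two-parameter model evaluated by numerical integration, and
    simulation tools for calibration experiments and patient samples.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, Rcpp, pracma
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
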