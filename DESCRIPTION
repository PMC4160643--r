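Package: oxhlia
Title: Time-Dose Modelling of Oxidative Hemolysis Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of erythrocyte survival kinetics from the
    oxidative hemolysis inhibition assay (OxHLIA) and related hemolytic
    bioassays. Provides a reparameterized Weibull survival model with an
    explicit half-life, closed-form derived kinetic parameters (maximum
    hemolysis rate, rate at the half-life, lag phase), phenomenological
    effector-modifier functions (linear, hyperbolic, sigmoidal, bell), and
    simultaneous bivariate time-effector nonlinear least-squares fitting
    with linearized parametric inference (Student-t confidence intervals,
    Fisher F consistency test, adjusted R-squared, residual diagnostics).
    Includes a seeded synthetic-panel generator, plain-text plate/long-table
    readers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
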