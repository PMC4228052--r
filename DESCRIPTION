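Package: utilicit
Title: Utility Elicitation from Risky Choice and Marginal-Utility Analysis
    of Simulated Dopamine Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for measuring von Neumann-Morgenstern utility functions
    from binary risky choices and relating them to reward prediction-error
    signals. Implements the PEST adaptive staircase and incentive-compatible
    psychometric estimation of certainty equivalents, fractile-method
    construction of a cardinal utility function with monotone piecewise-cubic
    spline fitting, marginal utility as the analytic first derivative,
    first- and second-order stochastic dominance tests on finite lotteries,
    out-of-sample validation via Deming regression, an inhomogeneous-Poisson
    spike-train generator whose phasic rates encode utility prediction
    errors, peristimulus response analysis (windowed rates, correlations,
    Hedges' g), and TD(lambda) learning driven by response magnitudes. A
    synthetic expected-utility-maximizing agent stands in for behaving
    subjects so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
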