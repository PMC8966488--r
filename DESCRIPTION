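Package: plastinorm
Title: Reaction-Norm Evolution of Breeding Date under Hard Selection with Costly Plasticity
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantitative-genetic model of the joint evolution of the intercept
    and slope (plasticity) of a linear breeding-date reaction norm on nutritional
    condition, under Gaussian stabilizing selection around a nutrition-dependent
    optimum, a direct cost of plasticity, and hard selection (environments
    contribute to the next generation in proportion to their mean absolute
    fitness). Provides exact per-environment selection gradients, fitness-weighted
    total responses, numeric and closed-form equilibria of the mean intercept and
    slope (including the small-slope-variance cubic and weak-mismatch
    approximations), and a vectorized individual-based Wright-Fisher simulator
    with infinitesimal-model inheritance used to validate the analytic layer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
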