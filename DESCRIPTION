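Package: evodoe
Title: Evolutionary Design and Optimization of Multi-Factor Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A human-in-the-loop genetic algorithm for optimizing multi-factor
    experimental conditions (e.g. cultivation media and pH for recombinant
    protein production) against a weighted multi-objective fitness function,
    with population-profiling convergence diagnostics, multigene
    genetic-programming symbolic regression to model the explored response
    surface, and perturbation-based sensitivity analysis that ranks the
    factors driving each objective. Includes a synthetic wet-lab oracle so
    the whole workflow can be exercised and tested without experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
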