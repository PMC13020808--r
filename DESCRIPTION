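Package: allocbias
Title: Performance-Based Reward Allocation: Shapley Benchmarks and
    Zero-One-Inflated Beta Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying self-allocation bias in performance-based
    cooperative reward division. Generates prime-judgement performance
    stimuli and symmetric allocation-task trial lists for simple, additive
    and disjunctive collective task criteria; derives contribution
    benchmarks from two-player coalition games via Shapley values;
    simulates cohorts of allocating agents with self-bias, social-value
    orientation linkage and performance down-weighting; and fits
    hierarchical zero-one-inflated beta regressions (MAP/Laplace or MCMC)
    with marginal-mean and marginal-slope contrasts, highest-posterior-
    density intervals and approximate leave-one-out model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
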