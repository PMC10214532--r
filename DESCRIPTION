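Package: mtbo
Title: Multitask Bayesian Optimization for Reaction Condition Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-task and multitask Gaussian-process surrogates over mixed
    continuous/categorical reaction condition spaces, with expected-improvement
    and q-noisy expected-improvement acquisition, Latin hypercube
    initialization, and closed-loop campaign runners for comparing single-task
    against multitask (transfer-learning) Bayesian optimization. Includes a
    synthetic reaction-yield benchmark family with tunable inter-task
    correlation for in-silico studies, and surrogate benchmarks trained from
    experiment tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
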