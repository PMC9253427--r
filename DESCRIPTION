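Package: adaptdd
Title: Adaptive Trial Generation and Model Comparison for Delay Discounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for model-guided adaptive intertemporal-choice experiments.
    Fits subject-level delay-discounting models (hyperbolic, exponential,
    quasi-hyperbolic, hyperboloid, modified hyperboloid, double-exponential,
    constant-sensitivity) to binary choice data by maximum likelihood through
    a softmax choice link, inverts the choice model to construct trials that
    evoke predetermined immediate-choice probabilities (including resolution
    rules for atypical trials), compares candidate models by out-of-sample
    prediction error across two experimental runs, and provides a
    synthetic-agent simulator for parameter-recovery and design validation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
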