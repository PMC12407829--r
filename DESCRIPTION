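Package: normbench
Title: Warped Bayesian Linear Regression Normative Models and a
    Sample-Size / Covariate-Shift Benchmark
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits warped Bayesian linear regression normative models of
    regional brain measures (cortical thickness, subcortical volume) with a
    cubic B-spline age basis and a sinh-arcsinh (SHASH) warped Gaussian
    likelihood, optimized by evidence maximization with Powell's conjugate
    direction method.  Produces deviation (Z) scores, centile curves and the
    model-fit metrics used in normative modeling (MSLL, SMSE, explained
    variance, Pearson correlation, ICC(2,1)).  Includes a seed-reproducible
    synthetic cohort generator, subsampling schemes that manipulate training
    sample size, age skew and sex balance, outlier-based clinical readouts
    (total outlier counts, SVC classification), mean-level transfer adaptation
    from a large reference cohort, and linear mixed-model summaries of
    benchmark results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    splines,
    jsonlite,
    lme4,
    e1071,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
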