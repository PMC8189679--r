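Package: tfactivity
Title: Transcription Factor Activity Inference by Constrained Bilinear
    Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers latent transcription factor (TF) activities from
    log-scale gene-expression matrices by factoring expression into a
    condition-independent matrix of control strengths (with per-gene
    baselines) and a condition-dependent matrix of non-negative TF
    activities, fitted by alternating constrained least squares with
    sign constraints on control strengths and perturbation-derived
    bounds on activities. Includes construction of qualitative TF
    network maps from ranked edge lists, generation of sign constraints
    from correlations or perturbation responses, benchmark metrics for
    TF-perturbation datasets (direction of perturbation, rank
    percentile, TF-mRNA correlation bootstraps), sigmoid and impulse
    time-course fitting with BIC model selection, and a synthetic
    benchmark generator emulating single-TF deletion and overexpression
    designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
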