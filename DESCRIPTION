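Package: ppglm
Title: Continuous-Time Poisson Process GLMs for Submillisecond Neural Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits continuous-time Poisson point-process generalized linear
    models to neural spike trains to infer functional coupling filters at
    submillisecond resolution. Provides two likelihood estimators that avoid
    binning the data: a stratified Monte Carlo estimator of the cumulative
    intensity integral, and a closed-form polynomial-approximate estimator
    built on analytic integrals of a scaled generalized Laguerre temporal
    basis. Includes binned-GLM baselines, a coupled-GLM spike-train simulator
    with known ground truth, cross-correlogram utilities, and a
    connectivity-screening workflow for putative excitatory connections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
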