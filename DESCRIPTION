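Package: cropdistill
Title: Process-Based Rice Yield Simulation and Convolutional Surrogate
    Distillation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A daily-step process model of irrigated rice growth and yield
    (developmental-index phenology, radiation-driven dry matter accumulation,
    and spikelet sterility from cool-summer damage and heat at anthesis),
    a seeded synthetic daily weather generator for multi-grid, multi-year
    experiments, and a distillation pipeline that trains a small
    convolutional neural network surrogate on simulator output and
    interprets it through positive gradient saliency profiles binned by
    developmental index.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
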