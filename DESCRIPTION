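Package: needmot
Title: Event-Driven Latent Models of Homeostatic Need and Motivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissociating homeostatic need from motivation in
    neural and behavioral time series. Builds event-driven latent time
    courses (stepwise predicted-deficit "need" and its leaky temporal
    accumulation, "motivation"), convolves them with a GCaMP6s calcium
    kernel to predict fiber-photometry signals, and fits candidate models
    to observed traces by multi-start bounded optimization with AIC
    comparison, leave-one-out cross-validation, Friedman tests and
    block-permutation nulls. Also implements threshold models of
    optogenetically evoked behavior probability, an agent-based go/no-go
    foraging simulation contrasting direct-need and accumulated-need
    policies, and a synthetic-data generator so the whole pipeline is
    testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
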