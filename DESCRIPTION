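Package: cndc
Title: Critical Nitrogen Dilution Curves for Multi-Cut Forage Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Construct and validate critical nitrogen dilution curves
    (Nc = a * W^-b) from multi-cut, multi-rate fertilizer field trials,
    diagnose plant nitrogen status with the nitrogen nutrition index (NNI)
    and the cumulative nitrogen deficit (Nand), and derive agronomically
    optimal fertilizer rates from quadratic yield-response fits. Includes
    a seeded synthetic trial generator that emulates the statistical
    structure of a two-fertilizer (urea vs controlled-release urea),
    four-rate, three-cut alfalfa experiment, so every stage of the
    pipeline is testable without raw field data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
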