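Package: desstab
Title: Rational Design of Deep Eutectic Solvents for Enzyme Stabilization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening and rational design of deep eutectic
    solvents (DES) as enzyme-stabilizing media. Integrates COSMO-type
    sigma-profiles into ten-region S-descriptors, converts DES recipes
    (HBA:HBD molar ratios plus water content) into mole-fraction mixture
    descriptors, fits first-order enzyme-inactivation kinetics to
    residual-activity time courses (Levenberg-Marquardt), and trains
    single-hidden-layer perceptron QSPR models that predict inactivation
    rate constants from mixture descriptors, with the chemometric
    validation battery (RMSEP, SEP, RPD, RER) and model-quality
    classification. Includes a synthetic-data generator for parameter
    recovery testing and a reproducible file-based pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
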