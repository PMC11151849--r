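Package: mycorun
Title: Surrogate Modelling and Genetic-Algorithm Optimization of Mushroom Substrate Formulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Models the mycelial running length and running rate of shiitake
    (Lentinula edodes) grown on substrates composed of bagasse, wheat bran and
    beech sawdust. Ships the published 64-substrate design tables, a calibrated
    replicate-level data simulator, a Box-Cox/min-max preprocessing stack, a
    single-hidden-layer perceptron surrogate trained by full-batch adaptive
    gradient descent, a real- and integer-coded genetic algorithm used both for
    hidden-layer architecture search and for substrate-composition optimization,
    five linear regression baselines evaluated under repeated eight-fold
    cross-validation, and an ablation-based variable sensitivity ratio (VSR)
    ranking of the model inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
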