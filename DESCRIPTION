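Package: elmmil
Title: Multiple Instance Learning with Extreme Learning Machines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-step multiple instance learning (MIL) built on the extreme
    learning machine: a randomly initialized single-hidden-layer network
    selects one representative "win-instance" per bag, and the output
    weights are then solved by regularized least squares on the selected
    instances. Supports bag-level classification (MUSK-style drug-activity
    data) and regression, with MUSK/C4.5-style bag CSV input and output,
    synthetic bag generators with known witness instances, bag-stratified
    repeated cross-validation, and grid search over the regularizer and
    hidden-layer width.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
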