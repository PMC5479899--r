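Package: neurohebb
Title: Neuromodulated Hebbian Learning in Competitive Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a three-layer Hebbian-learning neural
    network in which acetylcholine- and dopamine-like signals modulate
    synaptic plasticity. The representation layer learns by an online Hebbian
    rule under softmax lateral inhibition; a label-averaging classifier head
    decodes the representation and supplies the confidence and
    reward-prediction-error signals that drive the two neuromodulator release
    schedules. Includes readers and writers for the IDX image container, a
    generator of synthetic prototype-based digit datasets, training protocols
    (critical-period pre-training, pairing experiments, combined release
    schedules, grid search), and representation metrics (class preferences,
    neural selectivity, confidence-accuracy curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
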