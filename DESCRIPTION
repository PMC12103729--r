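Package: koopmanfes
Title: Koopman Model Predictive Control for FES-Driven Ankle Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven modeling and receding-horizon control of functional
    electrical stimulation (FES) applied to ankle plantarflexion and
    dorsiflexion during gait. Provides a switched nonlinear ankle simulator
    with saturating muscle recruitment and a stance-phase ground-reaction
    torque, observable dictionaries and delay embedding for Koopman lifting,
    per-phase extended dynamic mode decomposition (EDMD) operator
    identification, a switched linear predictor, and a phase-switched model
    predictive controller with a discrete algebraic Riccati terminal cost and
    a projected-gradient solver.  Includes a synthetic gait-data protocol and
    study pipelines for prediction accuracy and closed-loop tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
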