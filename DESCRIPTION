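Package: iongate
Title: Neural Ordinary Differential Equation Models of Ion Channel Gating
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Hybrid mechanistic/neural-network modelling of voltage-gated ion
    channel kinetics, with the hERG (IKr) potassium current as the working
    example. Provides Hodgkin-Huxley and three-state Markov gate models,
    voltage-clamp protocol representation and simulation with an adaptive
    Dormand-Prince 5(4) solver, a state-space estimation procedure that turns
    voltage-clamp current traces into (state, voltage, derivative) training
    tuples via per-step smoothing splines, feedforward neural-network gate
    models (full replacement, additive discrepancy, and rate-network variants)
    trained by derivative regression with Adam, candidate-model least-squares
    fitting, and evaluation tools including mean-absolute-error tables,
    state-space coverage maps and extrapolation diagnostics. Includes a
    synthetic-data study driver that demonstrates recovery of missing gating
    dynamics under model discrepancy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
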