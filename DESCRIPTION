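Package: topogate
Title: Spectral-Topographic EEG Decoding and Dual-Loop Adaptive
    Communication Gating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis framework for dual-loop neuro-adaptive
    human-machine teaming. Generates synthetic multimodal operator sessions
    (14-channel EEG, task events, communication attempts) with known latent
    workload; preprocesses EEG with zero-phase FIR filtering and artifact
    subspace reconstruction; builds sequences of interpolated
    spectral-topographic band-power maps; decodes operational neurostates
    (channelized attention, diverted attention, surprise/startle) and a
    continuous cognitive load index with a hybrid convolutional-recurrent
    network; trains a constrained multi-agent proximal policy optimization
    controller that jointly regulates pilot haptic assistance and an
    engineer-facing traffic-light communication gate; and evaluates
    session-level outcomes (communication breakdown errors, reaction time,
    overload exposure) with repeated-measures statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
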