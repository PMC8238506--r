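Package: lsoveto
Title: Two-Compartment Model of Inhibitory Veto in Lateral Superior Olive Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based two-compartment (soma and axon initial segment)
    model of a lateral superior olive (LSO) principal neuron, parameterized by
    inter-compartment coupling constants. Implements semi-analytic spike
    probability for binomially activated excitatory and inhibitory synapse
    populations, interaural-time-difference (ITD) tuning curves for different
    inhibitory synapse placements (soma versus axon initial segment), and the
    accompanying analysis statistics for click-evoked responses: three-point
    Hanning smoothing, tuning-curve halfwidth and 20-80% slopes, ITD-SNR,
    monaural/binaural summation ratios, post-synaptic-potential latency, the
    theta (Mann-Whitney) effect size, and ITD/IID cue-map coordinates. A
    synthetic-recording generator with closed-form ground truth supports
    end-to-end testing of the analysis pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
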