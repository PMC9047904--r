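Package: whiskdecode
Title: Decoding Whisker Deflection Intensity from Barrel Cortex Evoked Responses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Pipeline for classifying whisker-deflection intensity from
    multi-electrode barrel-cortex recordings. Provides a synthetic generator of
    labeled evoked recordings (slow UP/DOWN alternation, layer- and
    state-dependent evoked local field potentials, multi-unit bursts), LFP/spike
    band splitting and robust threshold spike detection, UP/DOWN state labeling
    from cumulative instantaneous firing rates, per-trial evoked-response
    feature extraction (onset latency, peak amplitude, positive rebound,
    time-normalized LFP, MUA latency/duration/rate), nonparametric
    significance grids (Wilcoxon rank-sum, Kruskal-Wallis with Dunn post hoc),
    threshold-crossing spike encoding of analog signals, a liquid state machine
    of leaky integrate-and-fire neurons with short-term plasticity and a linear
    SVM readout (with optional neuromorphic-hardware constraint emulation),
    a recurrent spiking network trained by surrogate-gradient backpropagation
    through time, conventional baselines (feed-forward net, LSTM, random
    forests), and a repeated-split evaluation protocol with state- and
    layer-conditioned breakdowns.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    e1071,
    randomForest,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
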