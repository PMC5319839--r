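Package: bcisim
Title: Closed-Loop Simulation of a Point-and-Click Intracortical
    Brain-Computer Interface
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A closed-loop simulator for point-and-click intracortical
    brain-computer interfaces (iBCIs). Provides a synthetic-participant
    generative model (cosine-tuned Poisson spiking, high-frequency LFP
    power features, click-state signatures and slow baseline drift), a
    broadband signal chain (common average referencing, spike-band
    filtering, 1-ms threshold-crossing detection, 150-450 Hz band power,
    per-block baseline estimation), a velocity Kalman decoder with
    intention-based recalibration and an online velocity-bias corrector,
    a two-state hidden Markov model click classifier with a PCA
    front end, selectable grid and keyboard workspaces with dwell and
    click selection, and the achieved-bitrate and correct-characters-
    per-minute evaluation metrics, so the whole decoding stack can be
    exercised and measured without any recorded neural data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
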