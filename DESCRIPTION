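Package: rtnfb
Title: Simulator-Backed Real-Time fMRI Neurofeedback Engine
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and testing closed-loop real-time fMRI
    neurofeedback protocols at the desk, without a scanner. Implements
    block-design session scheduling for alternating and grouped emotion
    designs, a ground-truth-known synthetic BOLD generator (double-gamma
    HRF, AR(1) noise, low-frequency drift, rigid-motion traces),
    region-of-interest percent-signal-change feedback against a
    sigmoid-weighted neutral baseline, cumulative linear support-vector
    machine decoding of distributed emotion patterns, feedback-to-color
    saturation mapping for a virtual-environment brain-computer
    interface, and an offline quality-control stage with motion-artifact
    flagging, discrete-cosine high-pass filtering and voxelwise GLM
    validation of planted effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    RNifti,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    jsonlite
Config/testthat/edition: 3
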