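Package: actrbold
Title: Cognitive Simulation and BOLD Prediction for Numeric Reasoning,
    Calculation and Perceptual Judgment Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A minimal ACT-R-style discrete-event simulator of three
    self-paced numeric tasks (number-series inductive reasoning, three-term
    calculation, and perceptual judgment), together with the model-based
    fMRI machinery needed to turn simulated module activity into predicted
    BOLD signal: binary demand functions, convolution with a gamma
    hemodynamic response function, percent-signal-change against a
    rest-block baseline, and area-under-the-curve summaries per region of
    interest.  Includes stimulus and block-design generators under the
    original task constraints, behavioral summaries and repeated-measures
    comparisons, grid-search calibration of the latency factor and
    problem-state change duration, and a synthetic-participant generator so
    that every stage of the pipeline is testable without real imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
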