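Package: exolift
Title: EMG-Driven Lumbosacral Load Estimation and Model-Based Exosuit
    Assistance Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a neuro-mechanical model-based controller (NMBC) for a
    cable-driven back-support exosuit, end to end. Provides an EMG-driven
    lumbosacral musculoskeletal model (stiff-tendon Hill-type musculo-tendon
    units, cubic-spline geometry surrogates of muscle length and moment arm,
    bounded adaptive simulated-annealing calibration) that decomposes L5/S1
    flexion-extension moments into active and passive components and estimates
    lumbosacral compression forces; two assistive-force controllers (the
    moment-proportional NMBC and a trunk-inclination-based baseline, TIBC);
    a synthetic stoop-lifting trial generator emulating metronome-paced
    box-lifting with 5 and 15 kg loads; and the evaluation metrics used for
    such devices (human-exosuit work loops, force-tracking RMSE,
    phase-resolved means and peaks, cumulative compression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
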