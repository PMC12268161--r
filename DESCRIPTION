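Package: burstloop
Title: Beta Burst-Driven Adaptive Deep Brain Stimulation Simulation and Gait Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing beta burst-driven adaptive deep
    brain stimulation (aDBS) of the subthalamic nucleus. Provides streaming and
    offline detection of beta-band burst durations from local field potentials,
    a single-threshold ramp-limited stimulation control policy with therapeutic
    window clamping, continuous and randomly adapting (energy-matched) control
    conditions, a calibration pipeline that selects the beta band, burst
    thresholds and therapeutic window from stimulation titrations, quantitative
    gait and bradykinesia metrics from force plates and wearable gyroscopes
    (freezing of gait, asymmetry, arrhythmicity, shank angular velocity, wrist
    RMS velocity), and ground-truth-labelled synthetic signal generators with a
    stimulation-dependent LFP plant for closed-loop testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
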