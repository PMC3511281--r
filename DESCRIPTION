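Package: optoresp
Title: Simulation and Analysis of Optogenetically Evoked Spike-Train Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing responses of extracellularly recorded
    neurons to pulsed optogenetic (channelrhodopsin-2) stimulation. Provides a
    synthetic spike-train generator built on gamma-renewal baseline firing and
    first-order light-gated channel kinetics, plain-text session input/output,
    rate/CV electrophysiological classification of striatal units, peri-stimulus
    time histogram construction with a 2-SD evoked-response detector, response
    magnitude, latency-to-peak and post-train suppression statistics, pulse-width
    and light-intensity dose-response analyses, and cohort-level contingency
    summaries with exact Mann-Whitney comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
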