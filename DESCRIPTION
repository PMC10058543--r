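Package: erpcnv
Title: ERP and Contingent Negative Variation Analysis for Cue-Go Visuomotor Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of event-related potentials (ERPs) and the
    contingent negative variation (CNV) in a cued visuomotor reaction-time task.
    Provides a ground-truth-known synthetic EEG generator (64-channel 10-20
    recordings with embedded P100/P150/N200/P300/P400 deflections and an
    RT-coupled CNV ramp), preprocessing (FFT resampling, zero-phase FIR
    band-pass, epoching, peak-to-peak artifact rejection, baseline correction),
    condition-wise ERP averaging with component amplitude/latency measurement,
    CNV mean and slope extraction at Cz, fast/slow performance splits at the
    subject and trial level, and electrode-wise t-maps with Benjamini-Hochberg
    FDR threshold recomputation, latency ANOVAs and CNV-RT correlation, plus
    scalp topography interpolation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
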