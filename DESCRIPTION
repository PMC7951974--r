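Package: spikesig
Title: Spike Signal Estimation from Calcium Fluorescence Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates neuronal spike signals from single-neuron calcium
    fluorescence traces with a small analysis-synthesis (signal-to-signal)
    1-D convolutional network trained by maximizing Pearson's correlation
    with the ground-truth spike train. Includes a Poisson-burst calcium
    trace simulator, readers and writers for the spikefinder column-CSV
    dialect, Gaussian smoothing of spike targets, patience-based training
    with the Adam optimizer, the spikefinder evaluation protocol (Pearson,
    Spearman and ROC-AUC at 40 ms bins), layer-wise response and filter
    frequency-response analyses, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
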