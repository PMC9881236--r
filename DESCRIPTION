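Package: cacf
Title: Coherence-Adaptive Clutter Filtering for Color Flow Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for color flow Doppler processing from focused complex
    baseband (IQ) receive channel data. Implements conventional color flow
    imaging (slow-time high-pass clutter filtering of beamsummed ensembles,
    2-D autocorrelation velocity estimation, and variance/power priority
    encoding) alongside coherence-adaptive clutter filtering (CACF), which
    selects a clutter filter per pixel by maximizing the short-lag spatial
    coherence (SLSC) of post-filter channel data. Includes a synthetic
    channel-data simulator with prescribed receive-aperture spatial
    coherence and slow-time spectra for desk-scale emulation of flow
    phantom experiments, an HDF5 channel-data container, ROI statistics,
    and a computational cost model.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    rhdf5,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
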