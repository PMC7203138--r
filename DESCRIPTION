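Package: cohdecode
Title: Coherence-Based Spectro-Spatial Filters for Decoding Neural Time Series
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs stimulus or task dynamics (finger-flexion traces,
    speech amplitude envelopes) from trial-aligned multichannel neural
    recordings such as electrocorticography. Per-electrode Wiener-style
    spectral filters are learned from the cross-trial complex coherence
    between neural features and the target signal, treating each trial as
    one realization of a random process, and their outputs are combined by
    least-squares spatial weights into a single prediction. Includes the
    standard preprocessing chain (zero-phase Butterworth filtering, power
    line notch, common average reference, low-frequency components and
    high-frequency band envelope extraction, anti-aliased downsampling),
    blocked k-fold cross-validation with Pearson and concordance
    correlation scoring, a random-phase surrogate test for coherence
    significance, K-means/LDA discriminability analysis of spatial
    weights, a ridge-regularized lagged temporal response function
    baseline, and synthetic data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    MASS,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
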