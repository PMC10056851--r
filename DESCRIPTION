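Package: scatcall
Title: Whale Call Identification with Wavelet Scattering Features
Version: 0.1.0
Authors@R:
    person("scatcall", "developers", email = "scatcall@example.org", role = c("aut", "cre"))
Description: Identification of low-frequency baleen whale vocalizations
    (blue whale B- and D-calls, fin whale 20-Hz pulses) in hydrophone
    recordings.  Implements a from-scratch 1D wavelet scattering transform
    with Morlet filter banks, an LSTM sequence classifier trained by
    backpropagation through time, and three comparator pipelines
    (least-squares SVM on scattering features, instantaneous-frequency
    features with an LSTM, and a scattergram-based convolutional network),
    together with a synthetic hydrophone-recording generator, the
    preprocessing chain (polyphase resampling, nearest-neighbour resizing,
    Hamming windowing, zero-phase Butterworth noise derivation), and a
    repeated random-split evaluation protocol with confusion-matrix
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
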