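Package: megmontage
Title: Regional Source Montages for MEG Data Review
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds regularized, noise-whitened, depth-weighted linear
    inverse operators ("source montages") that convert whole-head MEG
    sensor recordings into the waveforms of a small set of regional
    sources, for fast visual review of epileptiform activity. Includes a
    current-dipole forward model in a homogeneous spherical conductor for
    magnetometers and planar gradiometers, a synthetic 306-channel helmet
    and a canonical 29-region source layout, a sinusoidal dipole-burst
    simulator with band-limited background noise, and an SNR and
    detectability evaluation framework (baseline/signal window SNR in dB,
    detectability counts, regularization sweeps, cortical SNR maps).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
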