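Package: larvadenoise
Title: Acoustic Denoising for Early Monitoring of Wood-Boring Pest Larvae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for denoising substrate-borne feeding sounds of
    wood-boring beetle larvae recorded with piezoelectric probes in noisy
    field conditions. Builds SNR-controlled mixtures of pure feeding
    sounds and environmental noise, trains time-domain denoising networks
    (dilated convolutions with optional shortcuts) and frequency-domain
    masking networks (recurrent layers over magnitude spectrograms),
    provides a wavelet soft-threshold baseline, and evaluates denoisers
    with SNR increment, segmental SNR increment and log-spectral distance.
    A synthetic-signal module generates surrogate feeding pulses, ambient
    wood sound and environmental noises so the full pipeline runs without
    field recordings, and a small spectrogram classifier quantifies the
    downstream detection benefit of denoising.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    rlang
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
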