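Package: biopad
Title: Decoding and Analysis of Forehead-Mounted Multimodal Biosignal Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for working with a forehead-mounted multimodal biosignal
    acquisition pad: a bit-exact codec for its 168-byte framed binary stream
    (CRC-validated, with resynchronization), the analog front-end unit-conversion
    models that map ADC codes to microvolts, microsiemens and degrees Celsius,
    the digital filtering stack (IIR comb mains rejection and direct-form-II
    Butterworth low-pass), and per-modality analysis pipelines: EEG Welch
    spectra with alpha-band dominance and blink detection, electrodermal
    activity signal-to-noise and skin-conductance-response extraction, weighted
    moving-average skin-temperature response quantification, and pulse-rate
    estimation from motion-corrupted photoplethysmography via recursive
    least-squares artifact cancellation and FFT spectral-peak tracking with
    Bland-Altman agreement statistics. A seeded synthetic-session generator
    emulates the device's signals and stimulus paradigms end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
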