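Package: eegdwt
Title: Wavelet Band-Energy Analysis of Task EEG with Synthetic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discriminates depth-of-reasoning task conditions (picking,
    coordination, rest) in multichannel EEG via discrete-wavelet-transform
    relative band energies and the Theta/Beta ratio (TBR). Provides a
    synthetic EEG cohort generator with programmable condition- and
    stage-dependent band-power structure, a preprocessing pipeline
    (band-pass filtering, average re-referencing, down-sampling to 64 Hz,
    1-s epoching, baseline correction), periodized dyadic DWT band-energy
    extraction with frontal electrode selection, stage-binned two-way
    ANOVAs with Tukey HSD post hoc tests, and a reproducible end-to-end
    command-line workflow with EDF input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
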