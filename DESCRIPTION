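Package: mepkit
Title: Quantification and Recruitment-Curve Analysis of Motor Evoked Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating, screening, quantifying and modelling motor
    evoked potential (MEP) recording sessions. Sessions of EMG sweeps acquired
    over ascending stimulation intensities are validated and organized into
    per-subject records and multi-subject masters; sweeps can be band-pass and
    mains-notch filtered with zero-phase Butterworth filters; MEP epochs are
    quantified by area under the rectified curve, root-mean-square amplitude,
    peak-to-peak amplitude or onset latency; per-intensity mean responses are
    fitted with a four-parameter Boltzmann (generalized logistic) recruitment
    curve by restarted Nelder-Mead optimization; and fitted curves are compared
    across experimental conditions with MEP, stimulation and slope metrics
    normalized to a baseline condition. A fully synthetic session generator
    makes every stage of the pipeline testable without recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
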