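Package: echopatch
Title: Simulation, Beamforming and Cardiac-Function Analysis for Wearable
    Conformal Ultrasound Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for studying wearable conformal cardiac ultrasound
    imagers in silico: transducer array geometry (flat, orthogonal and
    curved, with surface-profile phase correction), transmit sequence
    design (plane-wave, mono-focus and wide-beam diverging-wave
    compounding), single-scattering radiofrequency channel-data simulation,
    delay-and-sum receive beamforming with coherent compounding, B-mode and
    M-mode image formation, an image-quality characterization suite
    (resolution, accuracy, dynamic range, contrast-to-noise ratio,
    signal-to-noise ratio, penetration depth, bandwidth, insertion loss),
    and an echocardiographic pipeline deriving left-ventricular internal
    diameters, fractional shortening, Simpson-disk volumes, ejection
    fraction, stroke volume, cardiac output, heart rate and Bland-Altman
    agreement from M-mode images and segmentation mask stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rlang,
    tibble,
    purrr,
    ggplot2,
    generics,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
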