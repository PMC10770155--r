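Package: fecgx
Title: Fetal ECG Extraction by Template Subtraction from Abdominal ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Non-invasive fetal electrocardiogram (fECG) processing from
    multi-channel abdominal ECG (aECG) recordings.  Provides FIR band-pass
    preprocessing, maternal R-peak detection by principal component analysis
    combined with a continuous-wavelet-transform (CWT) modulus-maxima
    detector, five template-subtraction variants for maternal ECG
    cancellation (plain median template, SVD subspace projection, linear
    prediction, global scaling factor, and segment-wise sequential-analysis
    scaling), fetal R-peak detection, beat-matching evaluation
    (sensitivity, positive predictive value, F1), fetal heart-rate
    estimation, a 124-wavelet detector benchmark, and a fully controllable
    synthetic abdominal ECG generator with ground-truth annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
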