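Package: ramanscreen
Title: Frequency-Selective Correlation Screening of Serum Raman Spectra
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Untargeted screening of clinical laboratory markers against serum
    Raman spectra. Implements asymmetric least squares (AsLS) fluorescence
    background subtraction, pairwise correlation of spectral vectors with
    marker vectors, constrained greedy frequency selection with explicit
    overfitting controls, random-marker null distributions with z-value
    significance, subset-stability resampling, and out-of-sample concentration
    prediction with sum-ratio scaling. Ships a synthetic-cohort generator that
    emulates fluorescence-dominated serum spectra (Lorentzian Raman peaks,
    smooth variable backgrounds, photobleaching, frequency jitter) so the full
    pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
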