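Package: ramanicg
Title: Dual-Modal ICG Fluorescence and Raman Spectroscopy Tumor Margin Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combined indocyanine green (ICG) fluorescence imaging and
    Raman spectroscopy of tumor margins. Implements penalized least-squares
    rejection of the ICG fluorescence baseline from Raman spectra with
    piecewise-linear repair of post-subtraction artifacts, band-wise
    gradient-boosted tissue classification over the fingerprint
    (800-1800 cm-1) and high-wave-number (2800-3050 cm-1) regions,
    SNR-based segmentation of fluorescence images into intensity regions,
    inter-modality agreement statistics (Cohen's kappa, concordance,
    rank/linear correlations), and spatial margin mapping with boundary
    overestimation quantification. Includes a synthetic-data module that
    generates two-class Raman spectra with concentration-scaled ICG
    backgrounds and co-registered two-dimensional tissue phantoms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    xgboost,
    jsonlite,
    yaml,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
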