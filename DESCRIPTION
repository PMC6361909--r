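Package: qfinger
Title: Quantified HPLC Fingerprint Evaluation and Fingerprint-Activity
    Modeling for Herbal Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-consistency evaluation of herbal-extract HPLC-DAD
    fingerprints. Implements the averagely linear quantified fingerprint
    method (ALQFM): joint qualitative (S_L) and quantitative (P_L, alpha)
    similarity scoring against a mean reference fingerprint with an
    8-grade quality scale; multi-wavelength fusion fingerprints;
    marker-compound calibration, content computation and the P_mC
    percent-of-mean content index; ascorbic-acid-equivalent (ASAE)
    antioxidant activity from DPPH-quench responses; hierarchical
    clustering of peak-area matrices; and PLS1 spectrum-effect modeling
    with cross-validated Q2, Hotelling T2 outlier screening, bootstrap
    Latin partition train/test splits and VIP-based marker discovery.
    Ships a reference dataset of 30 commercial glycyrrhiza extract
    batches and a synthetic fingerprint generator with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    mclust,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
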