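Package: mirspec
Title: Mid-Infrared Spectrochemical Image Analysis of Tissue Preparation Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mid-infrared spectrochemical imaging (MIRSI)
    of tissue sections, built to quantify how fresh-frozen (FF) versus
    formalin-fixed paraffin-embedded (FFPE) preparation alters hyperspectral
    absorbance data. Provides Otsu-based tissue/background segmentation,
    background-noise calibration, rubberband (lower convex hull) baseline
    correction, Savitzky-Golay second-derivative sub-band analysis with
    noise-calibrated (3-sigma) peak calling, per-band peak-occurrence
    statistics, composite-Simpson band integrals with FF/FFPE percent
    reduction, Gaussian sub-band fitting, and a Z-score/PCA/UMAP/logistic
    regression discrimination branch. Includes a synthetic hyperspectral
    tissue-cube generator with per-class Gaussian band structure, scattering
    baselines, spatially varying amplitude fields, detector noise, FFPE
    amplitude attenuation and the FFPE-specific 1026 cm-1 artifact band, so
    the whole pipeline is testable without instrument data, plus ENVI cube
    serialization and an end-to-end study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    glmnet,
    uwot,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
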