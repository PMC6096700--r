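Package: aquaspec
Title: Water Correction and Chemometrics for Infrared Microspectroscopy of
    Live Cells in Aqueous Media
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for transmission FTIR microspectroscopy of single live
    cells measured through bulk aqueous layers. Implements bulk-water removal
    by least-squares fitting of the 1500-1700 cm-1 region of each cell
    spectrum to a protein (Matrigel) reference jointly with its paired PBS
    spectrum, plus two literature correction methods for comparison
    (silent-region baseline flatness optimisation and iterative water
    re-addition). Provides the downstream conditioning chain (quality
    control, Savitzky-Golay smoothing and second-derivative conversion,
    vector normalisation, region cutting), PCA-compressed canonical variate
    analysis with nearest-centroid classification and stratified k-fold
    cross-validation, and a forward simulator of synchrotron FTIR
    measurements (Beer-Lambert band mixtures, pathlength-scaled water,
    detector saturation, paired PBS acquisition, drug-effect band
    perturbations) for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
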