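Package: nircoffee
Title: Qualitative and Quantitative Detection of Coffee Adulteration from
    Near-Infrared Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting adulteration of ground coffee
    (soybean, barley, chicory, corn at 10-40% mass fraction) from portable
    near-infrared reflectance spectra on a 228-point 900-1700 nm grid.
    Provides a synthetic linear-mixture spectra generator with multiplicative
    scatter, baseline drift and noise; Savitzky-Golay, standard normal
    variate and multiplicative scatter correction preprocessing and their
    chained combinations; wrapper wavelength selection by invasive weed
    optimization and a binary chimp optimization algorithm with
    classification-error-rate fitness; grid-searched support vector machine,
    neural network and random forest classifiers; and confusion-matrix
    evaluation with macro-averaged precision and specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    graphics,
    nnet,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
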