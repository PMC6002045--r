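Package: pestrisk
Title: Presence-Only Climatic Suitability Modelling and Pest Risk Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for presence-only species distribution modelling with a
    maximum-entropy (Gibbs) model fitted by L1-penalized likelihood over
    background points, and for turning fitted suitability surfaces into pest
    risk maps. Covers occurrence ingestion and spatial thinning, kernel-density
    sampling-bias surfaces, Pearson correlation screening of bioclimatic
    predictors, feature expansion (linear, quadratic, product, threshold,
    hinge), cross-validated model selection by omission rates and AUC,
    sensitivity-plus-specificity thresholding into suitability classes,
    pest-by-host risk overlays, and latitude-aware area change statistics
    between current and future climate slices. Includes a synthetic climate
    and occurrence generator with a known suitability truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    geosphere,
    jsonlite,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
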