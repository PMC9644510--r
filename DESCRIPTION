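Package: ihcscore
Title: Protein Expression Level Scoring and Biomarker Screening in
    Immunohistochemistry Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies protein expression levels (high, medium, low) in
    H-DAB immunohistochemistry images and screens candidate cancer
    biomarkers from expression changes between normal and tumour tissue.
    Provides linear spectral stain unmixing in optical-density space,
    extraction of the most protein-stained image patches with a
    Wasserstein-distance criterion for choosing the patch count, a
    1247-dimensional handcrafted colour descriptor (histogram, moments,
    coherence vector, correlogram, characteristic curves), stepwise
    discriminant feature selection, SVM/random-forest/neural-network
    classifiers under protein-level grouped cross-validation, and a
    screening stage that combines expression-change t-tests with
    subcellular-location-change P values. Includes a synthetic stained
    tissue image generator so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    MASS,
    e1071,
    randomForest,
    EBImage,
    igraph,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
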