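Package: octafd
Title: Fractal-Dimension Vessel Density Analysis for En-Face OCTA
    Angiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies macular vessel density on binarized en-face optical
    coherence tomography angiography (OCTA) images as a box-counting fractal
    dimension, evaluated over three partitions of the macula (ETDRS quadrants,
    hemispheric quadrants and central annuli) and two retinal layers. Includes
    nonlocal-means denoising, Otsu binarization, caliber separation of vessel
    masks into micro- and macrovascular components, a cohort statistics layer
    (group comparisons, ROC discrimination with DeLong intervals, correlation
    analysis), and a synthetic angiogram and cohort generator with known
    ground truth for validation and power studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    pROC,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
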