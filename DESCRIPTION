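Package: ocpam
Title: Organoid Analysis for Combined Optical Coherence and Photoacoustic Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of dual-modality optical coherence microscopy
    (OCM) and photoacoustic microscopy (PAM) imaging of tumour organoids and
    spheroids. Provides spectral-domain OCM A-line reconstruction and en-face
    projections, 3D organoid segmentation with watershed splitting, longitudinal
    single-organoid tracking by attribute-based bipartite matching, relative
    volume growth quantification with detection of drug-tolerant-persister
    (biphasic) growth kinetics, fluorescence live/dead viability scoring,
    a 32-feature radiomics texture extractor (first-order, grey-level
    co-occurrence and run-length families), gradient-boosted viability
    classification with stratified cross-validation, and OCM/PAM image fusion
    with phantom-based calibration and melanin-positive cell detection. A
    seeded synthetic-data module generates realistic organoid time series,
    fluorescence pairs, mixed spheroids, calibration phantoms and spectral
    interferograms for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    tiff,
    yaml,
    jsonlite,
    xgboost,
    pROC,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
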