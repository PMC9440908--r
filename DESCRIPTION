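Package: CicadaDH
Title: Population Calcium-Imaging Analysis of Spinal Dorsal Horn Neurons
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of two-photon population calcium imaging of
    superficial spinal dorsal horn neurons: rolling-percentile dF/F
    baselining and drift quality control, ROC-calibrated stimulus and ligand
    responder detection, vector-based sensory tuning, receptive-field grid
    mapping, pharmacological cell typing from Gq-GPCR agonist response
    profiles (CICADA) with k-means clustering, dorso-ventral depth
    assignment from a structural volume, and pre/post-capsaicin central
    sensitization reporting. Includes a synthetic-experiment generator with
    known ground truth for validation and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    jsonlite,
    cluster,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
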