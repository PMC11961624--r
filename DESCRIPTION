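Package: coroscreen
Title: Automated Detection and Risk Classification of Anomalous Aortic
    Origin of Coronary Arteries in Cardiac CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for screening coronary computed tomography
    angiography (CCTA) volumes for anomalous aortic origin of a coronary
    artery (AAOCA). Stages: procedural generation of labeled synthetic
    cardiac CT phantoms realizing the normal and anomalous coronary course
    taxonomy (interarterial, sub-pulmonic, pre-pulmonic, retro-aortic, high
    take-off); segmentation-driven localization of the aortic root and
    fixed-size physical region-of-interest cropping; deterministic intensity
    and geometry preprocessing; acquisition-artifact-aware augmentation
    (noise, blur, contrast, cardiac-motion ghosting, step-and-shoot slab
    misregistration); a cascaded three-task 3D squeeze-and-excitation
    residual classifier with seed ensembling trained by backpropagation;
    cutoff-sweep and bootstrap evaluation; and Grad-CAM++ volumetric
    saliency plus t-SNE embedding maps for interpretability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
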