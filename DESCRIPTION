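Package: craniomorph
Title: Cranial Morphometry from Segmented Head MRI and CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Geometry and statistics for whole-head tissue segmentations:
    brain-mask-guided anterior ROI cropping that standardizes measurements
    across differently defaced MRI datasets, per-class extracranial tissue
    volumetrics (skull, subcutaneous fat, temporalis muscle), tangent-normal
    skull-thickness estimation from binary skull masks (MRI- or CT-derived,
    with Hounsfield-unit thresholding for CT), and the segmentation-agreement
    statistics used to validate them (Dice, 95th-percentile Hausdorff
    distance, Bland-Altman limits of agreement, Gwet AC1). A deterministic
    digital head-phantom generator with analytic ground truth makes every
    component testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    EBImage,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'roi.R'
    'volumetrics.R'
    'thickness.R'
    'agreement.R'
    'phantom.R'
    'cli.R'
    'craniomorph-package.R'
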