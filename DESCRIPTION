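Package: spmap
Title: Spatial Perturbation Analysis of Stereo-EEG Implantation Adequacy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing whether a stereo-EEG implantation adequately
    sampled the seizure-onset zone from channel-level interictal biomarker
    rates. Channel rates are coupled with distances to a spatial reference to
    form a power-law spatial system whose goodness of fit is measured by the
    log-log Pearson correlation. The system's response to virtual removal of
    the seizure-onset zone, and to permutation of the spatial reference,
    yields perturbation-strength statistics, a ranked spatial-perturbation
    map, quadrant image features, an unsupervised clustering model of
    implantation adequacy with a Student-t probability read-out, and
    channel-sphere resection volumetrics. A seeded synthetic SEEG cohort
    generator provides well-sampled and poorly-sampled scenarios for
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    pROC,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
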