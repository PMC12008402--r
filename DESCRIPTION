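Package: vfoct
Title: Segmentation-Free Estimation of Visual Field Sensitivity from OCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for learning Humphrey visual-field sensitivities directly
    from volumetric macular OCT scans without layer segmentation. Provides the
    24-2/30-2/10-2 test-point grid geometry with laterality and vertical-flip
    index maps, quality-control filters (reliability indices, OCT signal
    strength, an automatic upper-eyelid-artifact rule, Anderson-Patella
    glaucoma eligibility), longitudinal pointwise regression labelling with
    validity periods and masked 122-value target assembly, a seeded generator
    of paired synthetic OCT-like volumes and visual-field series, a compact 3D
    convolutional regressor trained with a masked loss under patient-wise
    cross-validation with flip augmentation and test-time averaging, and a
    full agreement/error evaluation suite (pairwise RMSE/MAE, correlations,
    Bland-Altman limits of agreement, severity strata, pointwise error maps,
    Mann-Whitney group comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
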