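Package: crossmodAug
Title: Crossmodal Feature Augmentation for Partially Aligned Multimodal Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for clinical prediction from partially aligned two-modality
    cohorts, motivated by early detection of mild cognitive impairment (MCI)
    from conversational language markers with auxiliary neuroimaging markers.
    A pairwise alignment classifier is trained on the few subjects possessing
    both modalities; for subjects with only one modality it synthesizes an
    auxiliary feature vector in the other modality's space as a convex
    combination of the k highest-scoring bank vectors. Includes an elastic-net
    detection model with coefficient-based feature importance, stability
    selection for per-modality feature filtering, four straightforward fusion
    baselines (concatenation, score averaging, outer product, and their mix),
    a repeated random-split evaluation protocol with subject-level grouping,
    and a synthetic cohort generator with a shared latent structure for
    method development and testing without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, DimensionReduction, Software
RoxygenNote: 7.3.3
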