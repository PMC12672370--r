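Package: cyclebrain
Title: Spatiotemporal Decomposition of Dense-Sampling Structural Brain Imaging
    Across the Menstrual Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for whole-brain analysis of densely sampled longitudinal
    structural imaging in relation to gonadal hormone dynamics. Provides
    singular value decomposition of per-session gray-matter volume or cortical
    thickness maps concatenated across individuals into spatiotemporal
    patterns, penalized-spline generalized additive modeling of the temporal
    scores, per-individual time-series regression and Spearman association of
    the scores with square-root transformed estradiol, progesterone and their
    ratio, one-way MANOVA comparison of endocrine profiles, and voxel- or
    vertex-wise general linear models with threshold-free cluster enhancement
    and permutation family-wise error control. Includes synthetic generators
    for menstrual-cycle hormone series (typical, endometriosis,
    oral-contraceptive and male templates) and for hormone-coupled image
    stacks, so the full pipeline can be exercised and validated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
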