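Package: psvrmem
Title: Periodic Support Vector Regression Decoding of Orientation Working
    Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing remembered grating orientations from
    multivariate voxel patterns with a periodic support vector regression
    (pSVR) decoder, and for evaluating such reconstructions. Includes a
    generative simulator of orientation-tuned voxel populations (periodic
    covariance kernel with gamma-distributed tuning smoothness) and of
    delayed-estimation behaviour; cubic-spline temporal detrending, temporal
    moving-average and circular feature-space smoothing; leave-one-run-out
    cross-validated decoding with sinusoid label projection and atan2
    recombination; feature-continuous accuracy (FCA) and its label-balanced
    integral (BFCA); a von Mises mixture model of behavioural reports with
    constrained maximum-likelihood fitting; cluster-mass permutation
    inference over decoding timecourses; and nested across-subject
    optimisation of smoothing width and voxel count.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
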