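Package: pssmap
Title: Probabilistic Sweet-Spot Mapping from Deep Brain Stimulation Test Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise probabilistic stimulation mapping for intra-operative
    deep brain stimulation (DBS) test data. Builds per-voxel stacks of
    electric-field / improvement observations from volumes of tissue activated
    (VTA), computes probabilistic stimulation maps with four statistics
    (one-sided t-test, one-sided Wilcoxon signed-rank with Pratt zero
    handling, directional Bayesian t-test, linear mixed model), corrects type
    I error by Benjamini-Hochberg FDR or voxel-wise nonparametric
    permutations, and extracts binary probabilistic sweet spots via frequency
    masking and cluster-size filtering. Includes a synthetic cohort generator
    emulating the intra-operative stimulation-test protocol, and an
    evaluation suite (Dice overlap, centroids, leave-one-out cross-validated
    overlap-improvement correlation, consistency metrics, between-method
    tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    RNifti,
    jsonlite,
    lme4,
    lmerTest,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
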