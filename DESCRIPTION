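Package: permaccel
Title: Accelerated Permutation Inference for the General Linear Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Permutation inference for univariate and multivariate general
    linear models on imaging data (voxelwise) or plain data matrices, with
    six acceleration strategies: plain counting with few permutations,
    sequential negative-binomial early stopping, generalised Pareto tail
    refinement, analytic-moment (no-permutation) gamma p-values via
    Pillai's trace, empirical gamma (Pearson type III) moment matching,
    and exact low-rank matrix completion of the test-statistic matrix.
    Includes spatial statistics (cluster extent, cluster mass, TFCE),
    familywise error correction through the extremum distribution, FDR,
    Wilson confidence intervals for permutation p-values, and a synthetic
    evaluation harness measuring error rate, power, and resampling risk.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
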