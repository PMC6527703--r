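Package: foldscale
Title: Universal Scaling of Cortical Folding Within a Single Cortex
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests the universal cortical folding scaling law
    At*sqrt(T) = k*Ae^(5/4) within a single cortex. Implements discrete
    Gaussian curvature by vertex angle deficit on triangulated surfaces,
    the Gauss-Bonnet topological correction that reconstructs equivalent
    whole-cortex areas from cortical partitions (lobes), per-hemisphere
    scaling-exponent estimation by ordinary least squares and by a
    covariance-corrected errors-in-variables estimator, and cohort-level
    statistics: ageing trends of the scaling offset K, Alzheimer's
    disease versus control contrasts with Cohen's d and rank-sum tests,
    and bootstrap confidence intervals. Ships synthetic-surface and
    synthetic-cohort generators with known ground truth, readers and
    writers for OFF/PLY meshes and the tabular schemas, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
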