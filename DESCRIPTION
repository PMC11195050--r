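Package: mbmcia
Title: Multi-Block Multiple Co-Inertia Analysis via NIPALS
Version: 0.1.0
Authors@R:
    person("Analysis", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint dimensionality reduction for multi-omics data with shared
    samples. Implements multiple co-inertia analysis (MCIA) and consensus PCA
    (CPCA) through a stable multi-block extension of the non-linear iterative
    partial least squares (NIPALS) power iteration, with column-level and
    whole-block preprocessing, eigendecomposition-free variance explained,
    block-contribution weights, and out-of-sample projection of new samples
    into a trained global score space. Includes a seeded synthetic multi-block
    data generator with planted latent factors, plain-text readers/writers for
    dense (TSV/CSV) and sparse (MatrixMarket) blocks, and command-line entry
    points for decomposition, prediction and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
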