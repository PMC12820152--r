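Package: spatmf
Title: Spatial Metagene Pattern Recognition by Graph-Regularized
    Non-Negative Matrix Factorization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recognizes spatial metagene expression patterns in spatially
    resolved transcriptomics and spatial multi-omics data by non-negative
    matrix factorization regularized on an expression-weighted spatial
    neighborhood graph, with adaptive per-pattern weighting by a pattern
    significance score, sparsity and metagene-orthogonality penalties, and
    a multislice extension sharing one metagene matrix across tissue
    sections.  Downstream operators derive pattern-specific gene lists,
    spatially variable genes, spatial domains (k-means on filtered
    patterns) and denoised expression, and a planted-truth simulator
    supports end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    mclust,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
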