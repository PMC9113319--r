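Package: OmicSSVD
Title: Multi-Omic Integration by Elastic-Net Sparse Singular Value
    Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrates two or more omic data blocks (samples by features)
    into a single standardized extended matrix and factorizes it with a
    sparse singular value decomposition in which feature loadings are
    penalized by the Elastic Net. The number of nonzero loadings per latent
    factor can be tuned automatically with a Bayesian information criterion
    over a candidate grid. A chunked file-backed matrix backend lets every
    decomposition run out of core on matrices larger than memory. Includes
    latent-score cluster analysis with silhouette model selection, an exact
    t-SNE embedding of sample scores, and a shuffle-decorrelation simulation
    benchmark that scores feature-selection sensitivity and specificity
    across sparsity degrees.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    cluster,
    data.table,
    Matrix,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'OmicSSVD-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'penalty.R'
    'operators.R'
    'lanczos.R'
    'preprocess.R'
    'io.R'
    'ssvd.R'
    'tune.R'
    'chunked.R'
    'downstream.R'
    'tsne.R'
    'simulation.R'
    'pipeline.R'
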