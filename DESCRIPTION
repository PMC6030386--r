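Package: treeglmm
Title: Phylogeny-Regularized Generalized Linear Mixed Models for
    Microbiome Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts continuous or binary outcomes from microbiome OTU
    abundance profiles with a generalized linear mixed model whose random
    OTU effects carry a phylogeny-induced correlation structure. The
    correlation between OTU effects decays exponentially with patristic
    distance, so closely related taxa are encouraged to act alike; a power
    transform of relative abundances captures signals carried by rare taxa
    or by presence/absence patterns. Continuous outcomes are fitted by
    restricted maximum likelihood via a spectral decomposition of the
    kernel; binary outcomes by penalized quasi-likelihood. Includes
    cross-validated tuning of the phylogenetic-depth and abundance-weight
    parameters, a Dirichlet-multinomial simulator of OTU count tables with
    phylogenetically clustered outcome signals, a reusable preprocessing
    pipeline (outlier samples, OTU filters, size-factor normalization,
    winsorization), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    cluster,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
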