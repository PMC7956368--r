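Package: dissimspace
Title: Image Classification in Dissimilarity Spaces Built with Siamese Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies labeled images by learning a pairwise dissimilarity with
    Siamese convolutional networks, selecting per-class prototypes with
    supervised k-means, representing every image by its vector of learned
    distances to the prototypes, and fusing one-vs-all support vector machines
    across network topologies, prototype counts and input representations.
    Includes HASC relational descriptors (covariance and entropy/mutual-
    information matrices of low-level feature maps) as an alternative input
    representation, a synthetic spectrogram-like image generator for fully
    reproducible experiments, and accuracy/one-vs-all AUC evaluation with
    Wilcoxon signed-rank comparison of methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    e1071,
    Matrix,
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
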