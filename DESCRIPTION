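Package: ckametric
Title: Supervised Metric Learning by Centered Kernel Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns discriminative linear projections and layer-wise
    pretrained feed-forward networks by maximizing the centered kernel
    alignment (CKA) between a Gaussian kernel on projected features and a
    class-label kernel. Includes downstream k-nearest-neighbour, kernel
    support vector machine and neural-network classifiers operating in the
    learned space, multi-class evaluation statistics with bootstrap
    confidence intervals, and a synthetic generator of morphometric-style
    feature tables for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    kernlab,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    class,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
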