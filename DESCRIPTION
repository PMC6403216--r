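Package: codelcnn
Title: Detection of 1p/19q Co-Deletion from Targeted Copy-Number Profiles
Version: 0.1.0
Authors@R:
    person("AMC", "Pipeline Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for arm-level 1p/19q co-deletion detection from targeted
    next-generation-sequencing copy-number profiles. Reads per-bin log2
    copy-ratio tables (CNVkit CNR dialect) and SNP-array probe tables,
    summarizes chromosomes 1 and 19 as fixed-length signal vectors,
    harmonizes dense array profiles onto the targeted-panel grid by
    contiguous group averaging, balances classes with a from-scratch SMOTE,
    trains a two-branch ensemble one-dimensional convolutional neural
    network with residual blocks (implemented natively via Rcpp), makes
    deterministic rule-based 1p and 19q arm-deletion calls, interprets FISH
    nucleus counts, and evaluates classifiers with ROC curves, AUC and the
    Youden-index optimal cutoff. A self-contained simulator produces
    labeled synthetic copy-number profiles for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
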