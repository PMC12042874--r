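Package: canya
Title: Interpretable Convolution-Attention Modelling of Peptide Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements CANYA, a compact convolution-attention classifier of
    peptide aggregation propensity, together with the full analysis stack
    around it: labelling of deep mutational scanning aggregation scores
    (Z-test with Benjamini-Hochberg FDR control), replicate training with a
    KL-divergence interpretability score for model selection, position
    weight matrix extraction from convolutional filters, BLOSUM-based
    affinity-propagation motif clustering, Global Importance Analysis
    (single-motif, cluster, multiplicity, positional and interaction
    experiments), secondary-structure enrichment scoring, evaluation
    utilities with bootstrap confidence intervals, and an NNK-library
    simulator with a planted, known aggregation grammar for end-to-end
    validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
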