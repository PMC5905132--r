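Package: netmature
Title: Network Modules and Maturity Indices for Neuron Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies functional modules in a protein-protein interaction
    network that discriminate mature from immature neurons, by smoothing
    per-gene expression alteration scores with insulated heat diffusion,
    weighting interactions by smoothed-score concordance, clustering the
    topological overlap matrix with an adaptive dendrogram cut, and calling
    module direction with Wilcoxon signed-rank tests under
    Benjamini-Hochberg control. Trains per-module L1-regularised logistic
    classifiers and integrates them by cross-validated AUC weights into
    transcriptome-wide, discriminating-module and functionality maturity
    indices (tNMI, dNMI, NFI). Includes a synthetic-data generator with
    planted modules and directional effects so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
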