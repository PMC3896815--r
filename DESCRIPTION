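Package: reponet
Title: Network-Based Drug Repositioning from Literature and Expression Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts drug-disease associations by representing every drug and
    disease as a prioritized gene set. Initial gene lists from literature
    co-occurrence (a regularized log-odds connectivity score) and from ranked
    expression signatures (rank-list merging for drugs, a SAM-style moderated
    statistic for case/control disease data) are expanded into
    protein-interaction subnetworks, re-prioritized by degree, betweenness or
    closeness centrality, and assembled into Boolean entity-by-gene membership
    matrices. A per-disease L1-penalized logistic regression then writes each
    disease gene vector as a sparse combination of drug gene vectors, and
    predictions are scored against a gold standard by ROC/AUC with sampled
    zero-co-occurrence negatives. A synthetic-world generator with planted
    drug-disease modules makes the full pipeline testable end-to-end without
    any database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
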