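Package: ppnfuse
Title: Individual Networks and Person-to-Person Similarity Fusion for
    Multi-Modal Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds individual-specific co-expression networks per sample
    (Node Product and LIONESS), converts them into Person-to-Person
    similarity networks via node-value kernels or an edge-difference graph
    distance, fuses data modalities at the early (feature), intermediate
    (similarity) or late (prediction) stage -- including a Similarity
    Network Fusion implementation -- and classifies samples with a
    precomputed-similarity support vector machine scored by macro F1.
    Downstream interpretation covers edge-level differential co-expression
    with empirical-Bayes variance moderation and preranked gene-set
    enrichment. A synthetic-data generator with separable node-level and
    edge-level class signal makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    kernlab,
    igraph,
    limma,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
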