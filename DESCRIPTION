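Package: distentropy
Title: Distance-Entropy Scoring for Informative Sample Selection in Embedding Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores unlabeled pool samples by distance-entropy: the base-2
    Shannon entropy of a softmax distribution over negated Euclidean
    distances to per-class prototype vectors in an embedding space. High
    distance-entropy flags samples in the contested region between class
    clusters (informative for annotation); low distance-entropy flags
    redundant samples inside existing clusters. Includes ranked high/low
    selection, a seeded Gaussian-mixture generator with planted boundary
    samples, a trainable linear prototypical embedder, a pool-based
    acquisition-loop experiment harness with a nearest-prototype
    classifier, readers and writers for delimited feature tables, 2-D
    coordinate export for visualization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
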