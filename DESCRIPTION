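Package: bactipred
Title: Bacteriocin Prediction from Protein Sequence Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classify protein sequences as bacteriocins (ribosomally
    synthesized bacterial antimicrobial peptides) or non-bacteriocins.
    Computes a 1,103-dimensional candidate descriptor set (amino acid and
    dipeptide composition, pseudo and amphiphilic pseudo amino acid
    composition, composition/transition/distribution, secondary-structure
    summaries, sequence-order-coupling numbers, quasi-sequence-order
    descriptors, and PSSM bigrams), prunes it by Pearson correlation, and
    selects features with an alternating decision tree, a genetic-algorithm
    wrapper, or an L1-penalized linear support vector classifier before
    training and evaluating six classical classifiers with exact binomial
    confidence intervals, MCC and ROC AUC.  Includes a synthetic-data
    generator with controllable class signal so the full pipeline runs
    offline, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    class,
    e1071,
    glmnet,
    jsonlite,
    methods,
    randomForest,
    rpart,
    stats,
    utils
Suggests:
    caret,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
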