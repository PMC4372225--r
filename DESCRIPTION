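Package: fpqsar
Title: Frequency-Based Fingerprint Selection and Classification of Enzyme Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A QSAR toolkit for discriminating enzyme inhibitors from
    non-inhibitors using binary substructure fingerprints (PaDEL-style
    PubChem 881-bit matrices). Builds labeled datasets from IC50 activity
    tables with conflict removal and stratified splits, scores each
    fingerprint by its class-frequency difference (the FREQ approach),
    removes redundant bits by phi correlation, selects the best positive
    and negative fingerprints, classifies compounds by a signed sum-score
    rule, and evaluates interchangeable learners (random forest by
    default) with repeated stratified cross-validation, scaffold-class
    subsets and leave-class-out designs. Includes a synthetic
    class-conditional Bernoulli fingerprint generator with planted
    discriminative bits so the whole pipeline is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools,
    class,
    randomForest,
    e1071,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    pROC,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
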