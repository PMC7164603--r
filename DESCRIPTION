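Package: loadaboost
Title: Loss-Based Adaptive Boosting for Federated Learning on Clinical Tabular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A single-machine simulator for federated learning on clinical
    tabular data, centred on the LoAdaBoost FedAvg algorithm: clients whose
    local training loss exceeds the previous round's median client loss are
    adaptively retrained on a decaying epoch schedule, under a hard budget of
    3E/2 epochs per round. Implements the FedAvg baseline, the non-IID
    data-sharing strategy (a server-held IID pool distributed to clients at
    initialization), a synthetic ICU-style cohort generator with IID and
    covariate-sorted non-IID client partitioning, an ETL stage for
    MIMIC-style admission/patient/prescription tables, and the evaluation
    harness: rank-based ROC AUC, client-level k-fold cross-validation with
    repeats, the average-epochs complexity metric, and an exact one-sided
    Wilcoxon signed-rank comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
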