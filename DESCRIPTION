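Package: channelfed
Title: Channel-Based Federated Learning with Neuron Pruning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for privacy-preserving federated learning of dense
    feed-forward neural networks on distributed clinical cohorts. Clients
    train locally and upload only the gradient "channels" (one neuron per
    layer) with the largest Euclidean norms; the server aggregates the
    sparse updates with a decay factor and broadcasts its weights back.
    Includes average-percentage-of-zeros (APoZ) structured neuron pruning
    driven by a validation set, a federated-averaging baseline, from-scratch
    ROC and precision-recall evaluation, upload (trans-information)
    accounting, and a generator for sparse binary medication-exposure
    cohorts with a mortality outcome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
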