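Package: vqcbench
Title: Variational Quantum Classifiers Versus Classical Neural Networks on Clinical Tabular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for comparing variational quantum
    classifiers (VQCs) against classical feedforward neural networks on binary
    clinical tabular prediction tasks. Includes a dense statevector simulator
    with the RX/RY/RZ/CNOT/CZ gate set, basis, angle and amplitude (Mottonen)
    data encodings, a hardware-efficient RY/CZ ansatz with data re-uploading and
    quantum dropout, parameter-shift gradient training, a from-scratch
    feedforward network family, a synthetic heart-disease-like cohort generator
    with specified marginals and correlation structure, and an experiment suite
    for repeated-seed accuracy and sample-complexity studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    withr,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
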