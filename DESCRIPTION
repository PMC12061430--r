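Package: booldyn
Title: Synchronous Boolean Network Simulation of Hypoxia-Driven EMT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of synchronous-update Boolean regulatory
    networks, built around a hypoxia/mechanosensing/TGF-beta model of the
    epithelial-mesenchymal transition (EMT). Provides a BooleanNet-style rule
    parser and writer, a deterministic synchronous update engine with stochastic
    layers (per-node flip noise, per-step Bernoulli clamping for partial
    knockdown or hyper-activation, non-saturating environmental inputs),
    exhaustive and stochastic attractor detection with basin statistics per
    environment, signature-based phenotype classification, windowed experiment
    protocols over cell ensembles with apoptosis-aware live-time accounting,
    and a t-test based harness that scores simulated perturbation responses
    against curated in vitro assay directions. Ships self-contained fixture
    models (the EMT core switch and a compact hypoxia-EMT demonstration
    network) plus a seeded random-network generator, so every analysis is
    runnable without external files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
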