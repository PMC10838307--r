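Package: senomorph
Title: Senescence Detection from Nuclear Morphometry
Version: 1.0.0
Authors@R: person("Senomorph", "Developers", role = c("aut", "cre"),
    email = "maintainers@senomorph.dev")
Description: Detects cellular senescence from nuclear shape features.
    Provides feature extraction from labelled nucleus masks (three feature
    schemas mirroring common high-content and slide-analysis exports),
    classification-tree and random-forest senescence classifiers with
    cost-complexity pruning and an equal-weight voting consensus,
    performance metrics (accuracy, precision, recall, F1, ROC/AUC,
    Kolmogorov-Smirnov distance), a drug-screen pipeline with median-polish
    B-score normalisation, toxicity exclusion and hit calling, and a
    histology scoring system producing per-cell senescence scores (CSS)
    and per-sample tissue senescence scores (TSS). A synthetic-data module
    generates nucleus masks, two-population feature tables, screen plates
    with positional artifacts and tissue detection tables so the whole
    pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
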