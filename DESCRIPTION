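Package: boutonsort
Title: Volume-Based Sorting and Input-Selectivity Analysis of
    Electron-Microscopy Reconstructed Synaptic Boutons
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for sorting synaptic boutons reconstructed from volume
    electron microscopy into putative-origin subpopulations and for
    quantifying input selectivity on dendrite segments. Implements
    unbiased stereological sampling over annotated 3-D label stacks
    (counting frames with inclusion/exclusion sides), one-dimensional
    Gaussian mixture modelling of bouton volumes with BIC model
    selection, Monte Carlo estimation of volume cutoffs between adjacent
    subpopulations, volume-bin classification with putative-origin
    mapping, dendrite morphometry (caliber, cell-type flags, synapse
    density), association-rule mining of per-segment bouton co-occurrence
    (support, confidence, lift) and a confidence-weighted directed
    network with outstrength centrality. Includes a synthetic-data
    module that generates mixture-distributed bouton populations,
    segment/terminal co-occurrence datasets with controllable
    segregation, and small annotated label stacks, so the whole pipeline
    can be exercised end-to-end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    tiff,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    igraph,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
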