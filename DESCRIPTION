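Package: bsfc
Title: Burst-Suppression Coupling and Functional Connectivity for Anesthetized EEG-fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how isoflurane-induced EEG burst suppression couples
    to BOLD fluctuations and inflates functional connectivity in the anesthetized
    primate brain. Provides suppression-epoch detection from multichannel EEG,
    burst-suppression ratio computation, construction of hemodynamically
    convolved burst-suppression regressors, parcel-level BOLD preprocessing with
    configurable nuisance-regression/filtering order, per-run and group-level
    coupling models, whole-brain edgewise group statistics with network-based
    (component-extent) permutation correction, lobe-block standardized-residual
    permutation tests, seed-based connectivity, and a synthetic EEG/BOLD cohort
    generator with recorded ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
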