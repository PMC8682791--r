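Package: modkin
Title: Quantifying Cytosine-Modification Effects on DNA Duplex Stability
    and Replication Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for assays that probe how cytosine
    modifications (5mC, 5hmC, 5fC, 5caC) change DNA duplex stability and the
    speed of the replication machinery. Implements high-resolution melting
    (HRM) curve normalization, derivative computation and Tm calling;
    rule-based nucleus and chromocenter segmentation with intensity
    quantification and expression binning; the coefficient-of-variation
    statistic for focal RPA accumulation under polymerase inhibition, with
    pretreatment normalization and early-window slope estimation; molecular
    combing (DNA fiber) track classification and replication fork speed;
    growth-curve doubling times and S-phase substage kinetics; gel lane
    densitometry with background subtraction and ratio normalization; and the
    shared two-group statistics and boxplot summaries used for reporting.
    Seeded synthetic-data generators emulate every assay readout with
    recorded ground truth, so each quantification stage is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    pracma,
    stats,
    utils,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
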