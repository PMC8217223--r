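Package: vagsel
Title: Selectivity Analysis for Multi-Contact Vagus Nerve Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for selective abdominal vagus nerve stimulation
    experiments: detection of stimulation-evoked compound action potentials in
    nodose-ganglion microelectrode-array recordings by stimulus-triggered
    averaging with sliding-RMS smoothing and noise-referenced thresholds,
    binary-search amplitude thresholding, selectivity-index optimization over
    cuff contact pairs, conduction-velocity classification of C and A-delta
    fibers, nearest-neighbor and centroid somatotopy statistics with an exact
    Wilcoxon signed-rank test, and gastric myoelectric spectral analysis
    (dominant slow-wave frequency and normogastric power fraction). A
    ground-truth-labeled synthetic-data generator emulates the statistical
    structure of the recordings so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    signal,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
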