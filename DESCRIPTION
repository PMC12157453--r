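Package: surfdeliv
Title: Quantitative Surface-Delivery Metrics from Per-Cell Fluorescence
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how efficiently membrane proteins reach the cell
    surface from two-channel fluorescence data (microscopy images with
    segmentation masks, or flow-cytometry event tables). Computes
    background-corrected per-cell intensities, control-derived quantile
    thresholds, the stained-cell fraction f+, the mean surface signal, and
    the surface-delivery efficiency Esurface (the slope of a log-log
    dose-response regression on expression-binned means), with a logicle
    display transform. Includes differential-conservation scoring of
    multiple sequence alignment columns by Kullback-Leibler divergence
    between two sequence groups, the statistical comparisons used for
    replicate-level metrics (Welch, Dunnett, Tukey, Pearson), and synthetic
    data generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    tiff,
    mvtnorm,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
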