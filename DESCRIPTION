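Package: exomod
Title: Convergent Dual-Readout Screening for Exosome Release and Biogenesis Modulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for convergent exosome-modulator screens that
    pair an extracellular proximity readout (AlphaScreen-based ExoScreen
    counts per well) with an intracellular high-content readout (LBPA-positive
    granules per cell from three-channel fluorescence fields). Provides
    plate-level normalization to per-nucleus percent-of-control with Z'-factor
    assay QC and viability gating; nucleus/cell segmentation, spot detection
    and granule-to-cell linking for per-cell LBPA quantification; one-way
    ANOVA, Dunnett many-to-one comparisons and a permutation dose-response
    trend test; and a dual-readout decision table that labels each compound a
    release inhibitor, biogenesis inhibitor or biogenesis activator. A
    synthetic-data module generates plates and imaging fields with ground
    truth so the full analysis is testable at desk scale.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    mvtnorm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
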