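Package: synaprune
Title: Activity-Dependent Synaptic Pruning Analysis and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying and modelling NMDAR-dependent synaptic
    pruning in cultured hippocampal neurons. Detects PSD-95-like
    fluorescence puncta and computes densities per dendrite length,
    detects miniature and spontaneous excitatory postsynaptic currents
    (EPSCs) in voltage-clamp traces and classifies mono- versus
    poly-synaptic responses by a log10(area/duration) statistic, computes
    spine-fate neighborhood covariates (nearest-neighbor distance,
    neighbor activity, cluster counts, en-passant boutons) across two
    imaging timepoints, and provides a calibrated stochastic simulator of
    activity-dependent pruning under pharmacological conditions. Includes
    synthetic-data generators (spine maps, fluorescence images, EPSC
    traces) with exact ground truth for end-to-end validation, plus
    report-grade statistics mirroring common electrophysiology
    conventions (D'Agostino-Pearson normality, rank-based fallbacks,
    Dunnett and Tukey post-hoc tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    EBImage,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
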