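Package: AmygQuant
Title: Quantitative Analysis of Anxiety-Circuit Behavior, LFP, Patch-Clamp
    and Histology Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, synthetic-data-driven implementation of a
    quantitative workflow for studying amygdala inhibitory circuits and
    anxiety behavior: open-field trajectory geometry (center avoidance,
    zone entries, kinematics), local field potential conditioning and
    multitaper spectral analysis tied to position and risk-assessment
    events, miniature postsynaptic current detection and passive-membrane
    estimation from voltage-clamp sweeps, rule-based quantification of
    cFos-positive cells and perisomatic synaptic puncta, and the study's
    statistical layer (Grubbs screening, two-way factorial ANOVA with
    Tukey post-hoc tests, Kolmogorov-Smirnov comparisons). A synthetic
    cohort generator with planted ground truth makes every stage testable
    without animal recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    minpack.lm,
    deSolve,
    pracma,
    EBImage,
    car,
    jsonlite,
    yaml,
    ggplot2,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Electrophysiology, Software, Visualization
RoxygenNote: 7.3.3
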