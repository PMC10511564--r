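Package: ircontrast
Title: Inversion-Recovery Lesion-to-Liver Contrast Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of lesion-to-liver contrast in magnitude
    inversion-recovery (Look-Locker/MOLLI) liver MRI. Provides closed-form
    magnitude IR and spoiled gradient-echo signal models, a reproducible
    synthetic cohort generator (lesion entities, diameters, compartment T1
    values) with Rician-noise image rendering, three-parameter T1 fitting with
    polarity restoration and Look-Locker correction, deterministic ROI
    placement and the lesion-to-liver contrast (LLC) statistic, a
    repeated-measures nonparametric statistical battery (Friedman,
    Dunn-Bonferroni post hocs, Wilcoxon, Kruskal-Wallis), and a
    contrast-optimal inversion-time planner with field-strength scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
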