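Package: kinforce
Title: Single-Molecule Force Spectroscopy and Motility Analysis for Kinesin Motors
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule optical-tweezers force
    records and unloaded motility data for kinesin family motors, with an
    emphasis on kinesin-3 (KIF1A/UNC-104) force generation. Provides a
    stochastic motor-under-trap simulator with ground-truth event logs;
    segmentation of force traces into microtubule encounters, force-generation
    events, stall plateaus and detach/reattach clusters; iterative
    chi-squared (Kerssemakers-style) step finding and photobleach step
    counting; kymograph-derived motility statistics (velocity, run length,
    landing rate) with censoring diagnostics; Poisson bead-binding models and
    shared distribution fits; and ensemble difference distance matrix (EDDM)
    comparison of conformational ensembles with Wilcoxon significance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
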