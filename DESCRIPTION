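Package: gaitphase
Title: Interlimb Phase, Coordination Indices and Circular Statistics for
    Rodent Gait Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying quadrupedal locomotion from footfall event
    tables and two-dimensional joint-marker trajectories. Builds per-limb step
    cycles and spatiotemporal gait indices, computes limb-pair phase values
    with irregular-step classification against control-derived variability
    bounds, derives intralimb (proximal-distal joint angle) coordination,
    gross coordination indices (regularity, coordinated pattern, plantar and
    dorsal stepping indices), and postural stability metrics. Includes a
    bespoke statistical layer (two-proportion z tests in pooled and unpooled
    variants, circular descriptives, Watson's two-sample U2 with Monte-Carlo
    calibration) and a seeded synthetic gait generator, built on a von Mises
    phase-coupling model, that emulates footfall and kinematic data for fully
    reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
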