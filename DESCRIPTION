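Package: dopaphys
Title: Burst, Synaptic and Pharmacological Analysis of Dopaminergic Neuron Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for electrophysiological recordings from midbrain
    dopaminergic neurons. Implements the Grace-Bunney 80/160 ms burst criterion
    and spikes-within-bursts statistics for extracellular spike trains,
    interspike-interval regularity via Gaussian histogram fits, baseline-normalized
    firing-rate responses to drug application, detection and kinetic
    characterization of miniature inhibitory postsynaptic currents, evoked- and
    intrinsic-current measurements (GABA-evoked peaks, afterhyperpolarization
    charge transfer, hyperpolarization-activated sag current, passive membrane
    properties), and the nonparametric cohort statistics used to compare treatment
    groups. Ships a synthetic-data generator with known ground truth so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
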