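Package: nicocircuit
Title: Behavioral, Circuit and Synaptic Quantification of Nicotine Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A multi-modal analysis toolbox for quantifying the behavioral
    and dopamine-circuit effects of nicotine. Implements two-bottle-choice
    oral consumption analysis (artifact filtering, session windowing,
    preference and mg/kg/day dose), elevated O-maze and conditioned place
    preference scoring, in vivo spike-train response quantification
    (sliding-window firing rates, baseline normalization, burst %SWB),
    brain-region cFos coactivation network analysis (volcano statistics,
    correlation modules, Louvain communities, reorganization testing), 3D
    segmentation of fluorescent presynaptic boutons, patch-clamp current
    analysis (bi-exponential decay fitting, charge transfer, paired-pulse
    and AMPA/NMDA ratios, sEPSC detection), and a normality-gated statistical
    battery. Seeded synthetic-data generators with known ground truth make
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    minpack.lm,
    pracma,
    stats,
    tiff,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
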