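Package: kisspmf
Title: Umbrella-Sampling Free-Energy Profiles and Base-Contact Annotation
    for RNA Kissing-Loop Complexes
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis machinery for umbrella-sampling studies of RNA
    loop-loop (kissing) complexes. Reads multi-model PDB coordinates,
    computes the loop-loop centre-of-mass distance collective variable,
    annotates base-base relationships (Watson-Crick, non-canonical,
    stacking) from ring-frame geometry, reconstructs the potential of
    mean force along the loop-loop distance with the weighted histogram
    analysis method (WHAM), estimates per-point errors by a four-block
    procedure, aligns forward/backward profiles, and extracts docking
    free energies and hysteresis diagnostics. A synthetic-data module
    generates biased collective-variable samples from analytic free-energy
    functions (with optional AR(1) autocorrelation and planted hysteresis)
    and labelled idealized base geometries with known ground truth, so the
    whole pipeline is testable end-to-end without molecular-dynamics
    trajectories.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
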