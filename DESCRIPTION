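Package: pfdyn
Title: Longitudinal Place-Field Dynamics, Stability and Plasticity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-day two-photon calcium imaging of
    hippocampal CA1 place cells on a cued linear treadmill. Converts raw
    fluorescence to dF/F with significant-transient masking, builds lap-by-bin
    spatial activity maps, detects place fields with a spatial-information
    shuffle test and onset/reliability criteria, tracks place-field
    consistency across days (double-exponential cohort decay, memoryless
    random-process expectations, stability index), computes cosine-similarity
    context-discrimination indices and behavioral metrics, detects putative
    behavioral-timescale synaptic plasticity (BTSP) inductions and plateau
    potentials in imaging and membrane-potential data, and implements three
    generative models of place-cell stabilization (three-pool kinetic,
    cascade-state and progressive stabilization). Includes a synthetic-data
    generator that emulates the study design so every stage is testable with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
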