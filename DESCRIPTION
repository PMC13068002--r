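Package: traparray
Title: Poisson Pairing Statistics and Cytotoxicity Quantification for
    Microfluidic Trap Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing and analysing single-cell pairing
    experiments in bifurcated microfluidic trap arrays. Implements the
    Poisson and double-Poisson trap-occupancy model with empirical
    estimators, cohort taxonomy (empty, control, 1:1 singlet, multiplet)
    and goodness-of-fit; a lumped hydraulic-resistance model of the
    S-stage bifurcation network with occupancy-dependent flow diversion
    and shear estimates under pressure- or flow-driven boundaries; a
    seeded Monte-Carlo cell-loading simulator; a ground-truthed synthetic
    generator of multi-channel time-lapse trap-array image stacks and
    calcium traces; the trap-array quantification pipeline (straighten,
    split, count, intensity traces, tracer/PI colocalization death
    calling, division and escape exclusions, effector-to-target cohort
    cytotoxicity with significance tests); and classification of calcium
    flux traces into responder, non-responder and death-signature
    archetypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    pracma,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
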