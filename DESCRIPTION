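Package: preful3d
Title: Phase-Resolved Functional Lung MRI Ventilation Mapping from 3D Radial
    UTE Acquisitions
Version: 0.1.0
Authors@R: person("PREFUL3D", "Developers", email = "preful3d@example.org",
    role = c("aut", "cre"))
Description: Tools for free-breathing lung MRI ventilation analysis with a 3D
    ultra-short echo time (UTE) golden-means radial acquisition: DC self-gating
    and respiratory binning of radial spokes, regularized iterative SENSE
    reconstruction on a non-uniform Fourier (gridding) operator, registration
    of respiratory states, thoracic cavity segmentation, phase-resolved
    functional lung (PREFUL) regional ventilation (RVent) mapping and
    ventilation defect percentage (VDP) by k-means clustering, a
    threshold-based VDP for hyperpolarized-gas style ventilation images, and
    regional/statistical comparison machinery (eight-region partition, Dice
    overlap, Bland-Altman, mixed-effects correlation). A ventilating digital
    lung phantom with known defects provides end-to-end ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    lme4,
    optparse
Config/testthat/edition: 3
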