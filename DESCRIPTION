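Package: bnctbeam
Title: Multigroup Monte-Carlo Beam Modelling and Weighted Dosimetry for
    BNCT Collimator Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation toolkit for boron neutron capture therapy
    (BNCT) beam collimation studies. Provides a three-group Monte-Carlo
    neutron/photon transport engine for axisymmetric collimator plus phantom
    scenes, the four-component (boron, nitrogen, hydrogen, gamma) RBE/CBE
    biologically weighted dose model, beam-characterisation metrics
    (advantage depth, irradiation time at a mucosal prescription, 80%/50%
    isodose widths, air-gap sweeps), organ dose-volume-histogram statistics,
    and synthetic water/tissue/head-and-neck phantoms with noisy foil- and
    TLD-style measurement emulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    yaml,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'RcppExports.R'
    'beam_metrics.R'
    'bnctbeam-package.R'
    'materials.R'
    'collimator.R'
    'dosimetry.R'
    'dvh.R'
    'energy_groups.R'
    'phantoms.R'
    'pipeline.R'
    'scene.R'
    'source_model.R'
    'transport.R'
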