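Package: synaptomap
Title: Single-Molecule Tracking and Super-Resolution Analysis of Synaptic
    Membrane Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end quantification pipeline for single-molecule imaging
    of membrane proteins on neuronal dendrites: simulation of sparse-labelling
    tracking movies (uPAINT), dense localization tables (dSTORM) and FRAP
    recovery traces; wavelet-based spot detection with sub-pixel Gaussian
    localization, fiducial drift correction and dual-colour registration;
    frame-to-frame trajectory linking by optimal assignment with gap closing;
    MSD-based diffusion estimation with a resolution-derived slow-mobility
    threshold and confinement sizing; synapse segmentation from a postsynaptic
    marker channel with sorting, coverage, enrichment, dispersion and density
    statistics; nanodomain detection and FWHM sizing on super-resolved maps
    with trans-synaptic domain pairing; and diffusion-reaction FRAP model
    fitting yielding the free fraction and synaptic enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    tiff,
    EBImage,
    minpack.lm,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
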