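Package: burstFISH
Title: Quantification of smFISH Image Stacks and Stochastic Models of
    Transcriptional Bursting
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying single-molecule fluorescence in situ
    hybridization (smFISH) data in developing tissues and for comparing the
    results with a two-state (telegraph) model of transcription. The imaging
    side detects diffraction-limited mRNA spots in 3D confocal stacks by
    plateau-based threshold selection and 2D-to-3D object linking, calls
    bright nuclear transcription sites, normalizes their intensity to nascent
    RNA units, builds virtual cells from segmented nuclei by bounded 3D
    Voronoi tessellation, and computes spatially binned summary statistics
    (median mRNAs per cell, transcription-site frequency, Fano factor) with
    BCa bootstrap confidence intervals. The modelling side runs exact
    Gillespie simulations of promoter switching, initiation and decay,
    converts initiation times into probe-weighted nascent-RNA signal, pairs
    alleles, and sweeps burst size and burst frequency to predict
    transcription-site detection statistics. A synthetic-scene generator
    renders ground-truthed image stacks so the whole pipeline is testable
    without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    Matrix,
    Rcpp,
    boot,
    yaml,
    digest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, SingleCell, Transcription, Spatial, Visualization
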