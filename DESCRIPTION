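Package: nanodims
Title: Discrete-Mode Nano-DESI Mass Spectrometry Imaging with Elution Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing toolkit for discrete-mode nanospray desorption
    electrospray ionization (nano-DESI) mass spectrometry imaging of intact
    proteins. Discrete-mode acquisition parks the liquid-junction probe on
    each tissue location for a dwell period, so every pixel carries a
    time-resolved series of native mass spectra in which species elute with
    chromatography-like profiles governed by their solubility. The package
    provides a forward simulator of discrete- and continuous-mode scan
    streams from a tissue phantom, readers and a 4D (x, y, elution time,
    m/z) imzML store, pixelation of raw streams (spot sampling and time
    binning), multi-charge-state extracted ion chromatograms and averaged
    elution profiles with solubility classification, neutral-mass and lipid
    post-translational-modification mass-shift arithmetic,
    elution-time-filtered ion images, PCA/k-means tissue segmentation, and
    elution-time simplification of chimeric MS2 product-ion spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mzR,
    stats,
    tools,
    xml2
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
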