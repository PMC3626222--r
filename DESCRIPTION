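Package: holofilter
Title: Three-Dimensional Shift-Invariant Pattern Recognition for
    Digital Holographic Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for volumetric pattern recognition in digitally
    reconstructed holographic microscope fields. Implements angular-spectrum
    propagation of monochromatic complex fields, the equivalence between 3D
    correlation of a propagating field and plane-by-plane 2D correlation
    with a single spectral kernel, a trainable nonlinear correlation-filter
    cascade (correlation layers, pointwise cubic thresholds, squared-modulus
    readout) optimised by simulated annealing, synthetic scenes of
    rod-shaped microorganisms with off-axis hologram simulation and
    demodulation, and end-to-end 3D detection with peak finding and
    maximum-intensity projection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
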