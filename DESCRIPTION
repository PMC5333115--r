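Package: chiroptic
Title: Enantiomeric Excess and Conversion Analysis from Online HPLC-ECD Chromatograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for dual-channel (UV absorbance plus electronic
    circular dichroism) liquid-chromatography data. Detects and integrates
    chromatographic peaks, computes the Kuhn dissymmetry g-factor to obtain a
    concentration-independent enantiomeric excess from a single achiral-column
    injection, estimates reaction conversion from peak areas, simulates ECD
    spectra from quantum-chemistry transition tables (Boltzmann-weighted
    Gaussian band convolution) for absolute-configuration assignment, and
    performs L9(3^4) orthogonal-array range analysis for reaction
    optimization. Includes synthetic-data generators with known ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
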