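Package: phasorMP
Title: Spectral Phasor Analysis of Dye-Stained Microplastics in
    Hyperspectral Fluorescence Images
Version: 0.1.0
Authors@R:
    person("phasorMP", "developers", email = "phasormp@example.org",
           role = c("aut", "cre"))
Description: Identification and quantification of microplastic particles
    from lambda-stack (x, y, wavelength) fluorescence microscopy images of
    samples stained with a solvatochromic dye. Implements the per-pixel
    spectral phasor transform (normalized first Fourier harmonic of each
    emission spectrum), cursor-based segmentation of phasor clouds into
    polymer classes, connected-component particle extraction with size and
    composition statistics, reference-table identification of polymers from
    ATR-FTIR peak lists, and a fully seeded synthetic scene generator that
    emulates polymer-specific emission spectra and photon-counting shot
    noise so the whole pipeline is testable without an instrument. Includes
    a minimal multi-page TIFF reader/writer for lambda stacks and a
    command-line entry point covering simulate, phasor, classify, quantify
    and benchmark stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
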