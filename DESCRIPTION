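Package: phagomorph
Title: Bending-Energy Modelling and Morphometry of Autophagic Isolation
    Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the equilibrium morphology of the autophagic isolation
    membrane (phagophore) as an axisymmetric double-membrane cisterna with an
    open rim, by minimising the Helfrich elastic bending energy under an
    osmotic pressure difference obtained from the van't Hoff relation, with
    the total membrane area and the rim radius held fixed.  Provides shape
    descriptors linking model output to fluorescence morphometry, a synthetic
    three-dimensional fluorescence z-stack generator with diffraction blur and
    photon noise, and a morphometry pipeline that measures isolation-membrane
    size (half-perimeter), opening size (ring/punctum major axis) and
    region-of-interest intensities on maximum-intensity projections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
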