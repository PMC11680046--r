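Package: gdamage
Title: G-Values for Low-Energy Electron and X-Ray Damage to Plasmid DNA Films
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantification chain for the plasmid relaxation assay used in
    radiation-chemistry dosimetry of thin DNA films. Converts agarose-gel band
    intensities of irradiated plasmid films into conformation fractions, fits
    linear exposure-response curves, decomposes per-treatment yields into a
    nine-lesion taxonomy (strand breaks, crosslinks and enzyme-revealed base
    lesions via Fpg/Nth digestion), isolates the low-energy-electron
    contribution by tantalum-minus-glass substrate subtraction, and converts
    yields to G-values (damages per 100 eV). Includes oxygen-enhancement and
    direct/indirect decompositions, re-weighting of G-values over arbitrary
    0-30 eV electron energy distributions, and a synthetic forward model of
    the experiment so the whole pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
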