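Package: mmduplex
Title: Structural Analysis of Mismatch-Containing B-DNA Duplex Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to characterise the structural signature of base-pair
    mismatches in B-DNA duplex ensembles. Provides a reduced-atom synthetic
    duplex builder and trajectory generator with fully known ground truth,
    base reference-frame fitting and mid-frame (CEHS-style) intra- and
    inter-base-pair helical parameter decomposition, glycosidic (chi)
    conformer classification, hydrogen-bond pairing-scheme occupancies,
    base-pair breathing statistics, minor/major groove width profiles,
    cylindrical cation density maps, ensemble superposition and clustering,
    equipartition stiffness constants, and lesion-information-transfer
    profiles comparing mismatch against control ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
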