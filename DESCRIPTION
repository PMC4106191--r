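Package: ionlock
Title: Structural Analysis of Salt-Bridge ("Ion-Lock") Surfactant Protein C Peptide Mimics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing whether engineered surfactant protein C (SP-C)
    peptide mimics bearing Glu(-)-Lys(+) "ion-lock" salt bridges recover the
    alpha-helicity and membrane topography of the native, palmitoylated
    protein. Implements sliding-window Wimley-White whole-residue octanol
    hydropathy with an engaged/disengaged salt-bridge option, pairwise
    beta-sheet pairing-energy scanning with amyloid classification, amide-I
    infrared band deconvolution into secondary-structure fractions,
    polarized-ATR dichroic-ratio inversion to helix tilt angles,
    hydrogen/deuterium exchange compartment kinetics, deterministic synthetic
    data generators for all spectroscopic inputs, and a per-peptide report
    pipeline with a membrane-topology call.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
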