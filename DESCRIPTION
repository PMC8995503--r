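Package: kdrdesign
Title: Design and Quantification of Tunable 5' UTR Hairpin Attenuators for
    Knockdown-Replacement Constructs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for building single-transcript knockdown-replacement
    (KDR) expression systems in which a 5' UTR stem-loop "attenuator"
    titrates translation of a rescue gene.  Enumerates constrained hairpin
    stem sequences, scores their folding free energy with a nearest-neighbor
    thermodynamic model, selects panels of attenuators uniformly spaced in
    free energy, calibrates attenuation against measured
    percent-of-control expression, quantifies attenuation from two-channel
    fluorescence micrographs by pixelwise GFP/RFP ratiometry (with a
    seed-deterministic synthetic image generator for closed-loop
    validation), and assembles and validates full KDR construct sequences
    against their restriction-site cloning geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
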