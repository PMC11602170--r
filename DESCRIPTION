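Package: syntce
Title: Design, Thermodynamic Scoring and Assembly of Synthetic
    Translational Coupling Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates, scores, filters and ranks synthetic translational
    coupling elements (synTCEs): hairpin cassettes carrying a ribosome
    binding site in the loop and an overlapping stop-start codon (URAUG)
    that couple translation of a downstream open reading frame to the
    upstream one. Includes a nearest-neighbor free-energy layer (stem
    stability, anti-Shine-Dalgarno hybridization, start-codon spacing
    penalty, hairpin structure checks), IUPAC pattern-constrained stem
    randomization with in-frame stop filtering, compilation of parts
    (riboregulator switches, ORFs, linkers, synTCEs) into annotated
    multi-output operon transcripts and logic-gate layouts with
    per-junction validation, and quantitative utilities (geometric-mean
    fold change with quadrature error, feature regression, CFU counts).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
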