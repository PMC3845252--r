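Package: coopnma
Title: Protein-Protein Cooperativity in Collective Motions from Elastic
    Network Normal Modes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects cooperative behaviour of two proteins bound to the same
    DNA element from their collective motions. Builds anisotropic and Gaussian
    elastic-network models from PDB structures, extracts low-frequency normal
    modes, derives per-residue motion-magnitude and inter-residue-link
    rotation-angle curves, locates the maximally correlated equal-length
    segment pair between the two proteins of a pair by exhaustive
    sliding-window Pearson search, and classifies protein-protein
    cooperativity into single (S1, S2) and double (D) modes with signed
    subtypes under median, tertile, quartile and mean significance filters.
    Includes synthetic generators (bead complexes, planted-window curve pairs,
    controlled correlation tables) so the whole pipeline can be validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
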