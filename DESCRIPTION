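Package: seqflex
Title: Sequence-Based Side-Chain Flexibility and Disorder Discrepancy
    Profiling for Ion-Channel Segments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-residue intrinsic side-chain flexibility profiles
    from protein sequence using normalized B-factor propensity scales with a
    symmetric nearest-neighbour window, segment mean-flexibility indices
    (mBf), and their reciprocals.  Consumes per-residue intrinsic disorder
    tracks from external predictors, contrasts flexibility and disorder
    residue by residue through reciprocal discrepancy quotients with
    dispersion statistics, and flags residues whose two parameters are
    markedly disproportional.  Includes helix-class (pi versus 3-10)
    segment comparisons for transmembrane domains, an affine scale
    calibration against reference mBf anchors, and a seeded synthetic-data
    generator for end-to-end parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
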