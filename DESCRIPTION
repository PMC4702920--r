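Package: flexkit
Title: Conformational Flexibility Analysis of Redundant Protein Structure Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies local and global structural flexibility of a protein
    from multiple experimentally determined structures of the same chain.
    Parses PDB coordinate files, reconciles SEQRES against resolved residues,
    groups near-identical sequences at a 95 percent identity threshold with a
    master-slave multiple alignment, computes all-vs-all C-alpha RMSD by
    optimal rigid-body superposition, windowed local RMSD flexibility
    profiles, difference distance maps and contact map overlap, embeds the
    RMSD matrix by classical multidimensional scaling with mean-shift
    sub-cluster detection, and generates morphing trajectories between
    conformers by linear interpolation of distance matrices followed by
    restrained gradient minimization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
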