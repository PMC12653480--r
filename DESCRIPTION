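Package: orsite
Title: Conservation- and Structure-Based Prioritization of Functional
    Residues in Insect Odorant Receptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to prioritize candidate functional residues of
    seven-transmembrane insect odorant receptors from three evidence
    streams: per-column conservation of a protein family alignment,
    membrane topology (transmembrane helices, extracellular and
    intracellular loops), and a simplified alpha-carbon solvent-exposure
    score computed from a predicted structure. Includes JTT
    maximum-likelihood pairwise distances, Neighbor-Joining tree
    construction with bootstrap bipartition support, and synthetic
    generators for ortholog families and idealized helix bundles so the
    whole pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
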