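Package: argonet
Title: Topology-Anchored Conservation and Contact-Network Analysis of the
    Argonaute Superfamily
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structure-guided comparative analysis of the Argonaute protein
    superfamily. Provides a structure-anchored residue numbering scheme
    (lobe.SSE.position topology codes) bound to a reference multiple sequence
    alignment, normalized BLOSUM62 conservation scoring and group signature
    residue detection with hierarchical exclusion rules, geometric detection
    of noncovalent residue-residue contacts and their conservation across
    structure ensembles (signature contact networks), a nucleotide position
    labelling scheme for protein-nucleic-acid interfaces with backbone and
    C2'-OH classification, physicochemical interface statistics, mapping of
    disease missense mutations onto topology coordinates, cross-family
    comparison, and seeded synthetic-data generators with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
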