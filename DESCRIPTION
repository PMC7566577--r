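Package: trnaclover
Title: Cloverleaf Numbering and Structural Feature Annotation of tRNA Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates tRNA gene sequences with canonical (yeast tRNA-Phe style)
    position numbering by template-constrained cloverleaf folding or from provided
    dot-bracket structures, classifies secondary and tertiary base pairs (Watson-Crick,
    GoU wobble, purine-purine and other non-Watson-Crick pairs), and flags the unusual
    structural features of eukaryotic alanine tRNAs: the G3oU70 identity pair, a second
    wobble pair G30oU40 in the anticodon stem, the purine-purine tertiary pairs R15/A48
    and A54/A58, the extra D-loop residue U17 and purines at positions 16 and 60.
    Feature profiles are cross-tabulated by taxon, isotype and anticodon class with
    tRNAscan-SE score filtering and gene-copy weighting, and the co-occurrence of the
    two purine-purine pairs is quantified. A geometry module builds idealized base
    pairs from standard base geometries, classifies pairs from 3D coordinates into
    Leontis-Westhof edge/orientation families and measures C1'-C1' distances. A seeded
    synthetic-data module generates GtRNAdb-like gene sets with ground-truth structures
    and feature labels.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    bio3d,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
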