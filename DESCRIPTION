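Package: atomseq
Title: Sequences, Alignments and Atomic Structure Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A toolkit for computational molecular biology that represents
    biological sequences as alphabet-encoded integer arrays and biomolecular
    structures as columnar atom arrays.  Provides optimal global and local
    pairwise sequence alignment with linear and affine gap penalties scored
    by code-indexed substitution matrices, FASTA input/output, GenBank
    feature-table parsing, vectorized geometric measurements (distances,
    angles, dihedrals, backbone torsions), Kabsch superimposition, RMSD and
    RMSF, Shrake-Rupley solvent-accessible surface area, P-SEA secondary
    structure assignment, and readers/writers for PDB, PDBx/mmCIF and the
    binary MMTF format (including a full MessagePack and MMTF codec layer).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
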