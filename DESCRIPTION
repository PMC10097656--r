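Package: siftscif
Title: Residue-Level UniProtKB, Pfam, SCOP2 and CATH Annotations in PDBx/mmCIF Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes up-to-date residue-level correspondences between protein
    structure chains and UniProtKB sequences, projects Pfam, SCOP2 and CATH
    domain annotations onto structures, and writes the four SIFTS-specific
    PDBx/mmCIF categories (_pdbx_sifts_unp_segments, _pdbx_sifts_xref_db_segments,
    _pdbx_sifts_xref_db and the extended _atom_site items) directly into the
    coordinate file. Includes semi-global affine-gap sequence alignment with an
    exhaustive-enumeration reference, taxonomy-compatibility filtering, tandem
    repeat and split-domain segmentation with instance and segment identifiers,
    UniProt-numbering based Kabsch superposition, and a deterministic synthetic
    fixture generator for constructs with expression tags, truncations, point
    mutations, chimeras, repeats, unobserved residues and insertion codes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
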