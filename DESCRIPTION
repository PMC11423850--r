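Package: quatsite
Title: Quaternary-Structure Protein-Ligand Interaction Annotation
Version: 0.1.0
Authors@R:
    person("Q.", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for building quaternary-structure based protein-ligand
    interaction datasets from mmCIF asymmetric units. Generates biological
    assemblies from stored symmetry operators, partitions each assembly into a
    receptor (protein chains with >= 30 residues) and ligands (small molecules,
    metal ions, peptides, paired DNA/RNA chain groups), detects binding residues
    by a van der Waals distance rule, pairs nucleic-acid chains through
    inter-chain base pairs, computes solvent-accessible surface and buried
    interface areas, assesses ligand biological relevance against a
    crystallization-additive list, attaches experimental or consensus-regression
    binding affinities, removes redundancy with oligomer-aware chain similarity,
    and exports BioLiP-style single-chain splits. A synthetic-fixture generator
    makes every stage testable without downloading structures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
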