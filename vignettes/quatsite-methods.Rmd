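---
title: "quatsite: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{quatsite: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the scientific model the package implements, the
parameters a user may want to move, the choices made where the design was
genuinely open, and what the synthetic test world does and does not
establish. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The pipeline model

The unit of annotation is the **biological assembly** (quaternary
structure), not the deposited asymmetric unit and not a single chain.
Assemblies are built by applying the rotation–translation operators stored
in the mmCIF categories `pdbx_struct_assembly`, `pdbx_struct_assembly_gen`
and `pdbx_struct_oper_list`: each selected asym unit is transformed by
x′ = R·x + t. Operator expressions support comma lists, numeric ranges and
up to two parenthesized factors; two factors form the Cartesian product of
operator pairs, each pair composed as the left-to-right product of 4×4
homogeneous matrices (the convention used by mainstream mmCIF libraries).
Deeper nesting is rejected with an explicit unsupported-grammar error
rather than guessed at. Operators with det(R) ≈ −1 (reflections) are also
rejected: they do not occur in legitimate assembly definitions, and
silently accepting one would corrupt chirality. For multi-model (NMR)
inputs only the first model enters the pipeline. Modified residues are
renamed to their standard parents using `pdbx_struct_mod_residue` so that
sequence-derived logic (classification, identity, stoichiometry) sees
standard residues; coordinates are untouched and the original component id
is retained.

Each assembly is split into one **receptor** — every protein chain with at
least 30 observed residues (a chain of exactly 30 is a receptor chain; the
bound is inclusive) — and **ligands**: protein chains of 1–29 residues
(peptides), paired DNA/RNA chain groups, and every non-water non-polymer
residue group. A single-atom group whose element is in the packaged
metal/ion list is a metal ion; other single atoms (e.g. halides) remain
small molecules. Chain length counts residues with at least one resolved
non-hydrogen atom: interactions are structure-based, and unmodelled tails
cannot bind. Waters are never ligand candidates but are kept in the atom
table for output fidelity.

### Nucleic-chain pairing

Nucleic ligands are grouped, not split. Two chains are linked when they
share at least `min_pairs = 3` inter-chain base pairs; a chain of one or
two nucleotides keeps its pairing when *all* of its nucleotides are
base-paired with the partner chain (otherwise tiny chains could never
qualify). Multi-chain nucleic ligands are the connected components of the
accepted-edge graph — the only reading under which a pseudo-continuous
duplex of four chains forms a single ligand. Intra-chain pairs (hairpins)
are recorded but never create edges.

Base pairs come from a built-in geometric detector by default, so the
pipeline runs with no external binary: a residue pair is accepted when at
least `min_contacts = 2` atom pairs among the Watson–Crick edge atoms (N1,
N3, N6, N4, O6, O4, O2, N2) lie within `hbond_max = 3.5` Å **and** the
C1′–C1′ distance falls in [8.0, 11.5] Å, with each nucleotide joining at
most one pair (greedy by smallest mean contact distance, pair orientation
canonicalized so results are independent of atom order). The C1′ window
and the two-contact requirement are what reject stacked neighbours on the
ideal-helix fixtures while accepting canonical pairs; all three thresholds
are config keys. Output from an external secondary-structure program can
be substituted via `parse_dssr_pairs()` (JSON or text), which produces the
same record type. The detector counts all detected pairs, not only
canonical ones; it makes no attempt at non-canonical classification, and
unusual RNA architectures may pair incorrectly — a documented limitation
of the underlying heuristic.

### Binding sites, SASA and interface area

A receptor residue binds a ligand when any of its atoms lies **strictly**
closer to any ligand atom than r(a) + r(b) + `margin`, with
`margin = 0.5` Å and Bondi van der Waals radii (packaged table; unknown
elements fall back to the carbon radius 1.70 Å). Strict inequality follows
the rule's wording ("less than"); hydrogens are excluded throughout so
X-ray, NMR and cryo-EM entries behave uniformly. The production path uses
a spatial grid (cell size = 2·r_max + margin, 27-cell neighbourhood); an
independent all-pairs implementation (`binding_residues_bruteforce`) is
exported and the two are asserted equal on every fixture — the grid is an
optimization, never a semantic change.

Solvent-accessible surface area uses the Shrake–Rupley construction with a
deterministic golden-spiral point set (`n_points = 960` per atom,
`probe = 1.4` Å). The interface area of a receptor–ligand pair is

S = (S_prot + S_lig − S_com) / 2,

with all three terms computed in isolation under identical parameters (no
re-minimization). S is symmetric in the two roles by construction. At 960
points the isolated-sphere error is below 1 %, doubling the point count
moves totals by < 0.5 %, and rigid-body motions move S by well under 1 %
(the invariance test samples at 3840 points so discretization noise sits
below the 0.5 % bound being asserted). By default the interface is
computed for small-molecule and metal-ion ligands only — the annotation
regime the predicted-affinity branch targets — with a config flag to
enable it for any ligand.

### Biological relevance

The verdict hierarchy, in order: peptides and nucleic acids are relevant
without assessment; small molecules and ions **not** on the
crystallization-additive exclusion list are relevant by default; for
listed molecules, a site with fewer than `min_site_residues = 6` binding
residues on the *quaternary* structure means irrelevant, and a larger site
escalates to a keyword check — relevant if caller-supplied abstract text
mentions the ligand (or a supplied synonym) in the same sentence as
binding vocabulary, `needs_review` otherwise. Two single-chain-era
criteria — ligand occurrence count and binding-residue continuity — are
deliberately absent: on complete assemblies they reject exactly the
multi-chain pockets this representation exists to keep. The value 6 is a
calibration choice (the rule's published description never prints its
threshold) and is a config key. `needs_review` maps to the *irrelevant*
category in the three-way split, because the category invariant is
`relevant ⟺ verdict relevant`; a curator can promote entries by supplying
abstracts or overriding verdicts. The packaged exclusion list is a small
synthetic stand-in (common buffers, cryoprotectants, precipitant ions,
labelled as such in `inst/extdata/`); the full curated list can be dropped
in via `read_exclusion_list(path)`.

### Affinities

Experimental affinities enter through a TSV adapter and are normalized to
pKd = −log10 of the molar value (Kd, Ki and IC50 accepted; M through fM;
bad rows go to a rejects report, never abort a load). The consensus
predictor is ordinary least squares with intercept over three
physics-based scores — the published description says only "a regression
model", so the simplest faithful choice is fixed and recorded in the model
metadata, together with the target scale (pKd, also unstated in the
source). By OLS nesting, the in-sample consensus correlation can never
fall below any univariate score's correlation; `bootstrap_pcc_compare`
quantifies the improvement with a seeded percentile bootstrap (default
1000 replicates, significant when the 95 % CI excludes zero).

### Redundancy removal

Structures are first grouped by oligomeric state — a monomer and a dimer
of identical sequence are *never* compared. Within a state, two structures
are redundant when **any** pair of chains (one from each) exceeds
similarity 0.9; the wording "any" is implemented literally, with a
stricter all-chains mode left to future work. The relation is made
transitive via connected components (the published rule is silent on
transitivity; per-component representatives keep the retained set
conflict-free), and representatives are chosen by best resolution, then
lowest id. Sequence similarity is global Needleman–Wunsch identity
(match +1, mismatch 0, linear gap −0.5; identity = matches / alignment
length, with canonical argument ordering so co-optimal-alignment
tie-breaks cannot make the measure asymmetric). Structure-mode similarity
comes only through an external-tool adapter table; no structural aligner
is re-implemented.

## The synthetic test world

`make_structure_fixture` writes real mmCIF files (the parsers are always
on the tested path) with known ground truth:

- protein chains are extended four-atom backbone traces (3.8 Å rise) with
  seeded random sequences — no side chains, no secondary structure;
- B-DNA duplexes use ideal helical parameters (rise 3.38 Å, twist 36°)
  with Watson–Crick edge atoms placed at 2.9 Å donor–acceptor distances
  and C1′–C1′ = 10.4 Å, so the pair registry is known by construction;
- `ion_in_pocket` places a metal equidistant from 2–4 identical chains
  (two contact residues per chain); `dimer_interface_ligand` and
  `protein_dna_complex` are synthetic analogues of the worked examples
  from the motivating literature — a C2 homodimer with an interface
  inhibitor, and a dimer bound to a four-chain paired DNA ligand in which
  each receptor chain contacts exactly three DNA chains;
- `many_chain_giant` exercises >62-chain PDB splitting;
- `make_affinity_dataset` draws score triples iid N(0,1) with
  y = intercept + w·x + N(0, σ); σ defaults to 0.56, which places the
  strongest univariate correlation near 0.6 at n = 285 — the regime the
  consensus benchmark describes.

A green suite therefore establishes the *rules* — operator algebra,
thresholds, grouping, category logic, estimator algebra — on geometry that
satisfies the rules' preconditions exactly. It does not establish
robustness to real-structure pathology: missing atoms, alternate-location
soup beyond simple cases, non-canonical pairs, clashing assemblies, or
sequence-structure mismatches. The accession-anchored checks run on the
synthetic analogues, not on downloaded entries; with network access the
same assertions can be pointed at the real mmCIF files.

## Numerical and degenerate-input choices

- Alternate locations: highest occupancy wins, ties by altloc character —
  a single conformer before any geometry.
- mmCIF round trips preserve composition exactly and coordinates at the
  4-decimal write precision; legacy PDB at its 3-decimal format precision.
  PDB output refuses > 62 chains (`split_for_pdb` chunks chains in order
  of appearance and renames into `[A–Z a–z 0–9]`, emitting a bijective
  original→(file, new id) map).
- Assemblies with several stored definitions are all generated and
  processed independently, tagged by assembly id; when a file stores none
  (all legacy PDB input), a single identity assembly is built.
- Empty partitions are legal: no receptor or no ligands produces a
  structure-only entry rather than an error; per-file parse failures are
  quarantined to an errors report and the run continues.
- Entry ids are `{pdb_id}_{assembly_id}_{serial}` with serials assigned in
  (ligand kind, chain, residue) sort order; identical input and config
  reproduce byte-identical TSV exports.
- Carbohydrate/"other" polymer chains are routed as flagged residue-group
  ligands rather than dropped (an open point in the published rule set).

## Known limitations

- The geometric base-pair detector targets canonical double-helical
  geometry; heavily distorted or non-canonical RNA pairs should be fed in
  as parsed external output instead.
- The greedy sequence clustering is a deterministic stand-in for cd-hit
  style tools, quadratic in the number of sequences; it is intended for
  dataset-scale curation, not proteome-scale clustering.
- SASA is pure-R Shrake–Rupley; large assemblies (10⁵ atoms) will be slow
  compared to compiled implementations, though the spatial grid keeps the
  neighbour search linear.
- The keyword rule is an offline surrogate for literature text mining;
  `needs_review` is a first-class status precisely so that human curation
  can complete it.
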