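---
title: "Residue-level UniProtKB and domain annotations in PDBx/mmCIF files"
author: "siftscif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-level UniProtKB and domain annotations in PDBx/mmCIF files}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siftscif)
```

## The problem

Protein structures in the PDB carry author-assigned residue numbering that
rarely matches the numbering of the protein's reference sequence in
UniProtKB. Crystallised constructs are fragments of full-length proteins,
carry expression tags and engineered linkers, harbour point mutations, fuse
two proteins into chimeras, repeat a domain in tandem, and leave flexible
regions unobserved. Any residue-level comparison across entries — or
between an experimental structure and a sequence-numbered predicted model —
therefore needs an explicit mapping from each structure chain onto a
UniProtKB sequence, and a common place to keep it.

`siftscif` computes such mappings and writes them *into* the coordinate
file, as four additions to the PDBx/mmCIF content:

* `_pdbx_sifts_unp_segments` — residue ranges of each chain mapped onto a
  canonical UniProtKB accession and all of its isoforms, flagging the best
  mapping;
* `_pdbx_sifts_xref_db_segments` — residue ranges carrying Pfam, SCOP2 and
  CATH domain assignments;
* `_pdbx_sifts_xref_db` — the same information expanded to one row per
  residue, restricted to the best-mapped accession;
* four new `_atom_site` items placing the best mapping's accession,
  residue letter and UniProt number next to every atom, plus
  `pdbx_label_index`, a unique per-component index.

All SIFTS-specific categories reference the wwPDB `label_seq_id` numbering
(1..N, sequential per chain); author numbering and insertion codes are
carried alongside and never used as keys. Core categories are never
altered: augmentation only appends items and categories.

## The mapping procedure

For each chain, curated canonical accessions (an input — curation is a
human process upstream of this tool) are expanded to all isoform records.
The chain sequence is derived from the SEQRES-level categories, so
unobserved residues participate in the mapping; modified residues are
translated to their parent amino acid (`MSE` to `M`, and so on; unknown
components become `X`, which never counts as identical).

Each chain/record pair is aligned with an affine-gap aligner (match $+1$,
mismatch $-1$, gap run of length $L$ costing $-11 - (L-1)$). Three
terminal-gap conventions are implemented:

* **global** — the textbook Needleman–Wunsch/Gotoh path;
* **overlap** (`align_global` with free end gaps, the default) — a
  terminal gap run in *one* sequence at each end is free, so tags and
  truncations are not penalised, while unrelated sequences cannot
  cherry-pick a short interior island. This is the convention the
  exhaustive-enumeration reference (`align_enumerate`) scores and the one
  reported identities refer to;
* **local** (`align_local`) — both ends free; used internally as the
  anchor search.

The *mapper* (inside `candidate_mappings`) cannot rely on a single
monotone alignment: a chain holding two tandem copies of one protein maps
the same UniProt region twice, and an insert domain leaves the genuine
region as an interior island that an end-anchored alignment cannot reach.
It therefore (1) finds a local anchor, (2) trims it to the maximal-scoring
contiguous run of aligned columns (ties prefer the shortest, leftmost run,
so chance matches in foreign residues are not absorbed), and (3) recurses
on the unaligned chain flanks against the full record. A secondary
(flank) anchor is kept only if it aligns at least `min_segment_length`
residues (default 10) at or above the identity threshold — this is what
maps the second copy of a tandem repeat while rejecting spurious
similarity of tags and linkers.

Sequence identity is the fraction of identical aligned columns. A best
mapping must (i) be taxonomy-compatible, (ii) reach **at least 90%**
identity — the boundary is inclusive, so exactly 0.90 passes — and (iii)
align at least `min_coverage` (default 0.5) times as many columns as the
best-covering candidate of its group. The coverage rule is this package's
own addition: without it, a candidate explaining a 30-residue sub-region
at 97% identity could outrank a candidate explaining the whole chain at
80%, which inverts what "best mapping" means. Among qualifying candidates
the highest identity wins; ties prefer the canonical record, then the
lexicographically smaller accession.

**Taxonomy rule.** Two source organisms are compatible when they are
identical or when their ancestor walks intersect, where a walk is the
taxon plus at most `max_ancestor_levels` (default 2) ancestors and stops
once a species-rank node is included. Two strains of one species are
compatible; two species of one genus are not. The literature describing
the production pipeline states the rule only loosely ("one or two levels
up to species level"); the walk semantics here are one defensible reading,
parameterised so they can be changed without touching code. Chains with
no recorded source organism accept the curated mapping with a warning.

**Chimeras.** Each curated accession group yields its own best candidate;
`resolve_chimera` assigns every claimed residue to exactly one accession —
the claiming aligned run with more identical pairs wins, ties go to the
run starting further left, then to the smaller accession. All retained
accessions appear in the segments category, so no fusion partner is lost.

## Instances and split domains

Segments are maximal runs in which chain and UniProt numbering advance in
lockstep; a jump in either numbering, or an accession change, starts a new
segment. Unobserved residues do **not** break segments — segments are
defined on the sequence, and observedness is a per-residue flag.

One rule then assigns the two identifiers:

* if a segment's UniProt numbering still advances relative to the previous
  segment (`unp_start` > previous `unp_end`), it continues the current
  **instance** as an additional **segment** (a split domain: one instance,
  segment ids 1, 2, ...);
* if the numbering regresses or overlaps, a new **instance** begins (a
  tandem copy: instance ids 1, 2, ..., segment id reset to 1).

Domain definitions (Pfam in UniProt coordinates, SCOP2/CATH in either
UniProt or `label_seq_id` coordinates) are intersected with the mapped
residues and re-emitted as structure segments under the same rule, so a
repeated Pfam domain gets instances 1 and 2 and a domain split by an
insertion gets one instance with two segments.

## The synthetic-fixture generator

Because real archive entries require network access and curation context,
the package ships a deterministic generator (`make_uniprot_set`,
`make_taxonomy`, `construct_spec`/`make_entry`, `fixture_preset`) that
emulates the phenomena the mapping has to survive: N-terminal expression
tags, truncations, engineered linkers, tandem repeats, insert-domain
splits, two-protein chimeras, point mutations, 20% unobserved residues,
author insertion codes, selenomethionine, decoy records below 60%
identity, and a small ranked taxonomy with labelled compatible and
incompatible pairs. Coordinates are geometrically trivial (extended-chain
C$\alpha$ at 3.8 Å spacing with seeded jitter); superposition tests use
analytically transformed copies instead, so nothing about the tests
depends on realistic geometry.

Every fixture carries its full ground truth by construction. Two
generator-side guards keep that truth *exactly* recoverable rather than
approximately:

* **Junction sanitisation.** Wherever a mapped region abuts foreign
  residues (tag, linker, fusion partner), a chance letter coincidence
  could let the aligner extend the region by a residue or two at equal or
  better score, making the constructed mapping ambiguous. The generator
  trims element boundaries deterministically until no profitable or
  score-neutral extension exists. Boundaries interior to a split construct
  are frozen (trimming them would punch a hole into the reference
  numbering that a cheap mismatch bridge could exploit); the trim falls on
  the partner or tag/linker side instead.
* **Mutation placement.** Mutations are drawn only at positions interior
  to every isoform's coverage runs. A mutation outside one isoform's
  coverage — or at a coverage-run edge, where it is terminal to that
  isoform's alignment and silently dropped — would hand the isoform a
  strictly higher identity than the generating canonical record, making
  "recover the generating accession" unsatisfiable by *any* method.

A third guard applies to the below-threshold preset: its mutation count
has a floor of 12% of the mapped region, because a nominal 25% rate alone
does not *guarantee* a sub-90% construct — a lucky binomial draw can land
above the threshold, at which point a best mapping is the correct outcome
rather than a failure.

These guards are statements about what a well-posed recovery experiment
is, not tuning: with them, the pipeline reproduces the generated mapping,
instance/segment ids, conflict and observed flags exactly across hundreds
of seeds, and the heavily mutated preset (engineered to ~75% identity)
always yields "no best mapping". What passing these tests does **not**
show: performance on remote homologs (identity scoring, not a substitution
matrix, is used — appropriate because curated pairs are near-identical by
construction), on nucleic-acid chains, on microheterogeneity (the first
listed component is used, with a warning), or on real crystallographic
pathologies beyond those emulated.

## Superposition by UniProt numbering

With the `_atom_site` extension in place, residue equivalence across
entries is just equality of UniProt numbers. `coordinate_set` collects one
C$\alpha$ per mapped, observed residue (highest-occupancy altloc, ties by
altloc letter; the first copy of a repeated position), `pair_by_unp`
intersects two sets (at least 3 common positions required), and `kabsch`
computes the least-squares optimal proper rotation via SVD with reflection
correction. `multi_superpose` summarises several structures as the mean
RMSD over all unordered pairs, each pair independently superposed; an
all-to-first variant is available behind `method = "to_first"` since the
published figure does not state its averaging convention. A quaternion
(Horn) implementation, `kabsch_horn`, is exported purely as an
algebraically independent cross-check.

## Numerical and format choices

* Alignment scores with the default integer parameters are exact in
  double precision; traceback tie-breaks (diagonal, then gap in the
  UniProt sequence, then gap in the chain; corner-most terminal cell) make
  every output deterministic.
* Per-segment identity is the whole-candidate identity, not recomputed per
  segment; the format description shows identity at segment granularity
  without defining it, and a per-segment recomputation would make short
  segments noisy. Identity is serialized with four decimals.
* The mmCIF writer emits `loop_` syntax for multi-row categories and
  key-value pairs for single-row ones, quotes values containing
  whitespace or quotes, spills newline-containing values into semicolon
  text fields, and writes `.` for null. It is deterministic, so
  write–parse–write is a byte-level fixpoint; parsing preserves all values
  verbatim, which makes `parse(write(x)) = x` checkable as plain
  data-frame identity. Unknown extra items in SIFTS categories are
  preserved opaquely.
* SIFTS categories already present in an input are replaced wholesale on
  re-augmentation (the weekly-refresh semantics), so the pipeline is
  idempotent at category-content level.
* Multi-model entries: the mapping is computed once from the chain
  inventory and applied to all models, since sequence is model-invariant.
* Degenerate inputs: empty sequences, alignments with zero aligned columns
  (undefined identity), collinear coordinate sets, and insufficient
  superposition overlap all raise informative errors rather than
  propagating nonsense.

## Problem sizes in the shipped checks

The test suite and the acceptance script regenerate everything they use:
~10^4 random short sequence pairs against the exhaustive enumeration
reference, 504 fixtures (63 seeds x 8 presets) for exact ground-truth
recovery, a 100-entry corpus for serialization round-trips, and 1000
random point sets for the superposition oracle. These sizes keep the full
battery in the low minutes on one CPU while leaving each property with
enough replicates that a systematic defect cannot hide.

## Known limitations

* Accession curation and obsolete-accession resolution are inputs, not
  computed; a wrong curated accession yields a missing mapping, not a
  corrected one.
* Identity scoring is not a substitution matrix: mappings below ~60%
  identity are outside the intended regime.
* The taxonomy-walk semantics are one reading of a loosely specified rule;
  both the level count and the species truncation are parameters.
* `pdb_label`-coordinate domain definitions are projected per chain without
  repeat detection of their own; multiple instances arise only through
  UniProt-coordinate definitions.
* BinaryCIF, assemblies, anisotropic records and dictionary-driven
  validation are out of scope.
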