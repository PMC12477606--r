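---
title: "Methods: topology-anchored conservation and contact networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topology-anchored conservation and contact networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(argonet)
```

`argonet` compares Argonaute-superfamily proteins in a structure-anchored
coordinate system. This vignette documents the model behind each stage, the
parameters that matter, the numerical and design choices made where the
method left room, and what the synthetic benchmarks do and do not show.

## The topology coordinate system

All analyses run in the columns of a reference multiple sequence alignment.
A designated anchor sequence carries a secondary-structure annotation
(helix/strand spans in anchor residue numbering plus domain spans), from
which `build_topology_map()` derives one code per alignment column:
`LOBE.KIND<index>.<position>`, with kinds H (helix), S (strand) and L (loop).
Within each lobe (N or C), helices, strands and loops are numbered
independently in order of appearance; positions are numbered 1..k inside each
element. Loops are not annotated explicitly — every anchor residue between
two annotated spans belongs to the loop that separates them. Columns where
the anchor is gapped cannot receive their own anchored code; they attach to
the preceding anchored code with insertion indices 1, 2, ... (left-anchored,
so `C.H1.2.1` is the first inserted column after `C.H1.2`). Columns that
precede the first anchored column are rejected with advice to trim the
alignment: assigning them would require right-anchoring a prefix, which the
coding scheme does not define.

The lobe boundary is taken at the first C-lobe span: every anchor residue
from there on is C-lobe. The shipped `hago2_fixture()` is a synthetic anchor
constructed so that the published hAGO2 code examples (733 = C.L21.16,
573 = C.L11.2, 597 = C.S8.7, 358 = N.H7.2, and the rest of the bundled
mutant panel) are reproduced; it exercises the bookkeeping, including a
region where hAGO2 is gapped against the anchor, but does not claim real
secondary structure.

## Conservation scoring

Pairwise substitution similarity uses the normalized BLOSUM62 score

$$pBS(a, b) = \frac{B62(a,b)}{\sqrt{B62(a,a)\,B62(b,b)}},$$

which is symmetric, fixes the diagonal at 1, preserves the sign of the raw
matrix entry, and stays within [-1, 1] for BLOSUM62 (property-verified over
the full matrix in the test suite). `pBS <= 0` operationalizes a
"sufficiently changed" residue throughout the package.

The per-column normalized conservation score (NCS) is the mean over
unordered sequence pairs of `max(0, pBS)`. Gap policy: a pair with exactly
one gap contributes 0 and counts in the denominator (indel-prone columns are
penalized); gap–gap pairs are excluded (shared gaps must not inflate
conservation); an all-gap column scores 0. `X` is treated like a
zero-scoring symbol: any pair involving it contributes 0 and counts.
Clamping negative pair scores to zero keeps NCS in [0, 1]; since every
threshold in the method is group-relative (mean plus k standard deviations
over columns), this monotone rescaling does not move decisions. Group
summaries `mNCS`/`sdNCS` use the sample (n-1) standard deviation; with
population sd the thresholds would shift by O(1/n) and only marginal
candidates could flip.

## Signatures and the hierarchy rules

A group's signature candidates are the columns with `NCS > mNCS + 2 sdNCS`
(strict inequality, so a constant profile yields no candidates). The group
consensus at a candidate is the modal non-gap residue; ties exclude the
position — candidate lists are threshold-based and an ambiguous consensus
would make the downstream pBS comparisons arbitrary. Candidates found in a
parent signature with the same consensus are excluded; with a different
consensus they are kept only if `pBS(group, parent) <= 0` for every parent
covering the position; positions absent from all parents are kept. Hierarchy
soundness (no emitted entry shares a parent's consensus at its position) is
asserted after every build.

The universal signature is computed from three kingdom ancestral sequences
(precomputed inputs, aligned to the reference coordinates): a position
qualifies when all three pairwise pBS scores among the ancestor residues are
strictly positive (no gaps allowed) and the full-alignment conservation
exceeds `mNCS + 1 sdNCS`. Whether the underlying criterion should be the
minimum or the mean pairwise score is genuinely open; the package defaults
to the stricter minimum and exposes `method = "mean"`. The consensus is the
modal ancestor residue, with three-way ties resolved toward the Eukaryota
ancestor (documented, order-invariant otherwise).

Scoring a sequence against a signature averages `pBS(consensus, residue)`
over the signature positions; a gap (or X) at a signature position is
penalized with the minimum of the pBS matrix (-0.8165 for BLOSUM62) rather
than skipped, so truncated sequences score low instead of being quietly
flattered. Cross-family comparison (`cross_family_report()`) maps signature
positions into a second family's alignment through a structural anchor
mapping; signature positions whose code is absent from that mapping are
skipped, since the family has no structurally equivalent column to score.

## Contacts, conservation and SCNs

`detect_atomic_contacts()` evaluates geometric predicates with the engine's
published default thresholds, all overridable via `default_contact_config()`:
salt bridge 4.0 Å (anionic side-chain O to cationic side-chain N), hydrogen
bond 3.5 Å donor–acceptor heavy-atom distance (an explicit angle criterion
would need hydrogens, which the supported inputs lack), pi-cation 6.0 Å to
the aromatic ring centroid, pi-stacking 7.0 Å with ring normals within 30°,
t-stacking 5.0 Å with normals at 60–90°, and van der Waals
`d < r1 + r2 + 0.5` Å over a shipped element-radius table (C 1.70, N 1.55,
O 1.52, S 1.80, P 1.80); atoms of unknown element are skipped with a
warning. Ring normals come from an SVD plane fit of the ring atoms.

Aggregation collapses atomic contacts to unordered residue-pair edges in
topology coordinates with the union of observed types and the minimum
distance. Sequence-adjacent pairs (|Δresno| ≤ 1 within a chain) are dropped
to avoid trivial backbone edges. For predicted models, edges where either
residue's confidence is below 80 are dropped; the filter deliberately does
not apply to experimental structures.

Contact conservation of an edge is the exact fraction k/n of a group's
structural representatives containing it, with one representative per
protein. The default representative policy is deterministic: experimental
over predicted, then a guide-bound state flag, then higher mean confidence,
then ascending structure id. `mCC`/`sdCC` are computed over edges observed
in at least one representative — absent edges are not zero-padded, which
keeps the threshold scale-free in the number of conceivable pairs. The SCN
keeps edges with `CC > mCC + sdCC` that touch at least one signature
position; the universal SCN additionally requires the threshold to hold in
both subgroup networks, each against its own mean and sd, because the more
structurally variable prokaryotic group would otherwise dominate. Tie-breaks
for "most conserved contacts" listings are a stable sort by descending cc
then ascending code pair.

## The nucleic-acid interface

Guide positions are labelled from the 5' end except the last three, counted
from the 3' end (`3T`, `3T-1`, `3T-2`), which keeps the PAZ-anchored 3' end
comparable between guides of different lengths. Target positions are an
input annotation (`-k` matched, `B-k` bulge/mismatch); the package never
infers base pairing from geometry. Bulge-labelled contacts are carried in
all outputs but excluded from every aggregate statistic (shared interface,
signature interface, backbone and C2'-OH fractions). A nucleotide atom is
backbone if it belongs to the phosphate/sugar set; any contact type touching
`O2'` counts as a C2'-OH contact. Fractions are pooled over all edges across
a group's structures by default (a per-structure averaging mode exists),
whereas interface charge is reported per protein — distributions of
per-protein values are what group comparisons need.

## Mutations and assay categorization

Missense records are mapped through the protein's own residue numbering
(counting non-gap residues) onto codes, cross-checked against the aligned
sequence (a reference mismatch is a record-level error naming both
residues), and annotated with all applicable nested signature memberships —
collapsing to the most specific set is a presentation choice left to the
caller, and both views can be derived from the output. Cancer-exclusive
positions are codes with at least one somatic record and no
population-variation record in any paralog. Domain densities normalize by
both domain size and dataset size, so a uniform spread scores 1 everywhere
and the densities weighted by domain share always sum to 1.

Speckle categorization uses a one-sided Wilcoxon rank-sum test (mutant
lower), Benjamini–Hochberg adjustment jointly across the panel, and the
mutant/WT ratio of mean counts, with strict boundaries: Impaired below 0.25,
Reduced in [0.25, 0.50), Retained otherwise or when non-significant. Exact
p-values are used for tie-free arms of at most 8 images; larger or tied
panels use the midrank normal approximation with continuity correction.

## Synthetic data: what it emulates, and what it does not

The generators produce every input type with planted, serializable ground
truth, all driven by one integer seed through independent named streams.

* `synth_alignment()` emulates the nested clade structure (pAgo; eAgo =
  PIWI + AGO; mAGO inside AGO) with defaults of 40/20/20/12 sequences over
  200 columns — large enough that group-relative thresholds are stable, small
  enough for fast tests. Background columns are i.i.d. around a per-column
  consensus at identity 0.30 (a realistic remote-homolog level), gap rate
  0.05; planted columns are fully conserved within their group with a
  consensus drawn from the residues scoring `pBS <= 0` against the
  background consensus. Kingdom ancestors echo the universal positions and
  carry a discordant residue pair everywhere else, modelling divergence
  outside universal positions. `planted_noise` erodes planted conservation
  for degradation studies.
* `synth_structure_ensemble()` plants residue-pair contacts at exact
  frequencies (`ceiling(f * n)` members) using idealized coordinates: home
  atoms on a wide grid plus one dedicated, isolated pair of carbon atoms
  3.5 Å apart per planted edge. This realizes each geometric predicate
  exactly and nothing else; it does not emulate realistic side-chain
  packing, and is not meant to.
* `synth_na_complex()`, `synth_mutation_tables()` and
  `synth_speckle_counts()` realize interface edges, exclusive-mutation sets
  and negative-binomial count panels (size 8, WT mean 40, 9 images per arm,
  matching a three-replicate, three-image design) the same way.

Passing the planted-recovery tests therefore demonstrates that the
statistics, thresholds and bookkeeping are implemented correctly — it does
not demonstrate robustness to real-data pathologies (alignment errors,
heterogeneous structure quality, annotation noise), which no synthetic
benchmark of this kind can certify.

## Degenerate inputs and numerical notes

All-gap columns score 0; single-member groups are rejected; empty signatures
and empty SCNs are input errors for the operations that would divide by
them; positions without incident contacts have mean CC 0 (with a message);
zero-denominator interface fractions raise an undefined-value error naming
the counts. Contact-conservation values are exact small-integer ratios, and
the acceptance checks compare them with `==` rather than tolerances.
Chains with at least half nucleic residue names are classified nucleic
(tolerant of modified residues); predicted-vs-experimental auto-detection
treats constant-per-residue B-factors within [0, 100] as pLDDT.

## Problem sizes

The test suite and the acceptance script run entirely at desk scale: a
29-366 sequence synthetic alignment, ensembles of 10 structures of ~20
residues, 200-case randomized oracle sweeps, and 200-replicate power checks
for the assay categorization. These sizes were chosen so the full suite runs
in well under a minute while keeping every threshold statistic
(mean + k sd over columns or edges) estimated from dozens-to-hundreds of
observations.

## Known limitations

* Secondary-structure annotation of the anchor is an input; the package does
  not compute it from coordinates (no DSSP-like step), and only PDB-format
  coordinates are read (no mmCIF).
* The hydrogen-bond predicate is distance-only in the absence of hydrogens;
  highly polar near-misses can be over-called relative to angle-aware tools.
* Base pairing for target labelling is annotation, not geometry.
* The exact normalization of the conservation score used by other
  implementations varies; the choices here (Karlin-style pBS, zero-clamping,
  the stated gap policy) are documented and the thresholds are relative, but
  absolute position counts from other toolchains are not expected to
  reproduce bit-exactly.
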