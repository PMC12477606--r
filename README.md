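# argonet

Topology-anchored conservation and contact-network analysis of the Argonaute
protein superfamily.

Argonautes bind small nucleic-acid guides and match them to complementary
targets, in roles ranging from prokaryotic host defense to eukaryotic RNA
interference. The fold (N-L1-PAZ-L2 lobe plus MID-PIWI lobe) is conserved
across all domains of life while the sequences have diverged enormously, so
comparing family members residue-by-residue only works in a coordinate system
anchored on structure. `argonet` implements that workflow for people studying
protein-family evolution on structural coordinates: comparative analysis of a
structure-guided reference alignment, detection of clade signature residues,
conserved residue-contact networks, the nucleic-acid interface, and the
mapping of disease mutations onto all of the above.

## The coordinate system and statistics at the core

* **Topology codes.** Every alignment column gets a structure-based
  identifier `LOBE.SSE<index>.<position>[.<insertion>]` (e.g. `N.H7.2`, the
  second position of the seventh N-lobe helix), anchored on a consensus
  secondary-structure annotation. Columns where the anchor is gapped become
  insertion codes (`C.H1.2.1`). `map_residue()` / `code_to_residue()`
  translate between a protein's own residue numbers and codes.
* **Conservation (NCS).** Per column, the mean over sequence pairs of
  `max(0, pBS)`, where `pBS(a,b) = B62(a,b) / sqrt(B62(a,a) B62(b,b))` is the
  normalized BLOSUM62 score (diagonal 1, sign-preserving). A group's
  signature candidates are columns with `NCS > mNCS + 2 sdNCS`; candidates
  conserved as the same residue in a parent group are excluded, and diverged
  candidates are kept only when `pBS(group, parent) <= 0`.
* **Universal signature.** Positions where the Bacteria/Archaea/Eukaryota
  ancestral sequences agree (all pairwise `pBS > 0`) and the full-alignment
  conservation exceeds `mNCS + sdNCS`.
* **Contact conservation (CC).** Noncovalent contacts (salt bridge, hydrogen
  bond, pi-cation, pi/t-stacking, van der Waals) are detected geometrically,
  aggregated to residue-residue edges in topology coordinates (predicted
  models filtered at pLDDT >= 80), and scored as the exact fraction of a
  group's structure representatives containing the edge. The signature
  contact network (SCN) keeps edges with `CC > mCC + sdCC` touching at least
  one signature position; the universal SCN requires the threshold in both
  the eukaryotic and prokaryotic subgroup networks.
* **NA interface.** Guide nucleotides are labelled 5'-based except the last
  three (`3T`, `3T-1`, `3T-2`); target positions are `-k` (matching guide
  position k) or `B-k` (bulge/mismatch, excluded from aggregate statistics).
  Contacts are classified backbone/base, with ribose `O2'` (C2'-OH) contacts
  flagged; interface physicochemistry uses Henderson-Hasselbalch side-chain
  charges at pH 7 and scaled Kyte-Doolittle hydropathy.
* **Mutations.** Missense tables are mapped onto topology codes, annotated
  with nested signature memberships and interface membership;
  cancer-exclusive positions are those with somatic mutations but no
  population variation in any paralog. Speckle-assay outcomes are classified
  Impaired / Reduced / Retained from one-sided Wilcoxon rank-sum tests with
  Benjamini-Hochberg correction and mutant/WT mean-count ratios.

Every stage is testable without external downloads through seeded synthetic
generators with planted ground truth (`synth_alignment()`,
`synth_structure_ensemble()`, `synth_na_complex()`,
`synth_mutation_tables()`, `synth_speckle_counts()`).

## Worked example

```r
library(argonet)

# translate between hAGO2 residue numbers and topology codes
fx <- hago2_fixture()
map_residue("hAGO2", 733, fx$alignment, fx$topology_map)
#> [1] "C.L21.16"
code_to_residue("hAGO2", "C.S8.7", fx$alignment, fx$topology_map)
#> [1] 597

# run the full synthetic pipeline and check planted-truth recovery
res <- run_pipeline(list(seed = 1))
res$recovery
#>                stage precision recall
#>  signature_universal         1      1
#>       signature_pAgo         1      1
#>       signature_eAgo         1      1
#>       signature_PIWI         1      1
#>        signature_AGO         1      1
#>       signature_mAGO         1      1
#>                  scn         1      1
#>         na_interface         1      1
#>     cancer_exclusive         1      1

res$network
#> Contact network 'synthetic': 3 edges over 10 representatives, mCC 0.5333, sdCC 0.4509

res$speckles[, c("variant", "ratio", "p_adjusted", "category")]
#>        variant     ratio  p_adjusted category
#>  impaired_like 0.0952381 0.000360183 Impaired
#>   reduced_like 0.2517007 0.000360183  Reduced
#>  retained_like 0.8276644 0.116494480 Retained
```

Precision and recall of 1 mean every planted signature column, conserved
contact, interface edge and cancer-exclusive position was recovered exactly
and nothing spurious was reported. The contact network's three edges carry
conservation 1.0 / 0.5 / 0.1 — exactly the planted frequencies. The speckle
panel classifies a ~10% ratio as Impaired, ~25% as Reduced, and a
non-significant change as Retained.

A thin command-line wrapper is included at `inst/cli/argonet.R`
(`Rscript argonet.R simulate --seed 1 --out runs/demo`).

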