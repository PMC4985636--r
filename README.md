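# ptbscreen

Structure-based screening of peptide specificity for phosphotyrosine-binding
(PTB) domains.

PTB domains are adaptor modules that recognize NPXY/NXXY-motif peptides,
phosphorylated or not, and sequences flanking the motif tune the affinity.
All-atom simulation with MM/PBSA can rank a handful of candidate peptides
but is far too expensive for proteome-scale screening. `ptbscreen`
implements the fast residue-level alternative: extract the per-position
**binding pockets** from one peptide-bound template structure, **thread**
each candidate sequence onto the template register via its motif tyrosine,
and score the complex with a **statistical contact pair potential**,

```
S(peptide) = sum over positions i, pocket residues j of E(a_i, b_j)
```

where a residue pair is "in contact" when any two of their atoms lie within
4.5 Å, position 0 is the motif tyrosine (N-terminal flanks negative, as in
Tyr(−5)), phosphotyrosines are mimicked by glutamate before scoring, and
lower (more negative) scores predict tighter binding. Predictions are
evaluated against experiment with Pearson correlation on ΔG = RT ln Kd and
with ROC/AUC on binder / non-binder panels.

The package also provides hydrogen-bond inventories (N···O donor–acceptor
distances), Kabsch superposition RMSD, identity-based redundancy clustering
of domain sequences, and a synthetic-data generator that builds toy
complexes with exactly known contact maps and peptide panels with planted,
tunable binding signal — so the whole pipeline is testable without any
downloads.

**Note on the potential.** The packaged 20×20 contact matrix
(`inst/extdata/contact_potential_synthetic.tsv`) is a *synthetic* potential
with the qualitative structure of published contact potentials
(hydrophobic pairs favorable, salt bridges mildly favorable, like charges
repulsive); it is generated by the closed form in
`synthetic_contact_matrix()`. For production screening, supply a published
matrix (e.g. Betancourt–Thirumalai) to `load_matrix()` in the same
triangular text format.

## Worked example

```r
library(ptbscreen)

# A synthetic template complex: 13-mer peptide QNGYENPTYKFFE bound in a
# hydrophobic groove, one pocket residue for most peptide positions.
pdb <- tempfile(fileext = ".pdb")
cx <- make_complex(
  n_domain_residues = 12, n_peptide_residues = 13,
  contacts = data.frame(pep = c(2,3,4,5,6,7,8,10,11,12),
                        dom = 1:10, distance = 4.0),
  peptide_seq = "QNGYENPTYKFFE", domain_seq = "FILWYVMFLIAR",
  seed = 11, path = pdb)

template <- parse_pdb(pdb, domain_chains = "A", peptide_chain = "B")
pockets  <- build_pockets(compute_contacts(template, cutoff = 4.5))
pockets
#> <ptb_pockets> peptide positions -8..4 (Y = 0); 10 occupied pockets, 10 contacts

# Score a labeled panel with planted signal and benchmark it
potential <- load_matrix()
panel  <- make_panel(pockets, potential, n_binders = 100, n_nonbinders = 100,
                     effect_size = 3, kd_coupling = NULL, seed = 42)
scores <- score_panel(panel, pockets, potential)
report <- benchmark_report(scores, labels = panel[, c("id", "label")])
report$roc
#> <ptb_roc> AUC = 0.952 (100 binders vs 100 non-binders, 198 points)
```

An AUC of 0.95 means a randomly chosen true binder outscores (scores below)
a randomly chosen non-binder 95% of the time; the planted separation of 3
matrix units is recovered by the threading + pocket-sum scoring path. The
same `benchmark_report()` call accepts `affinities =` (Kd or ΔG) and then
reports the Pearson r between computational score and experimental free
energy; on the packaged six-peptide affinity panel
(`inst/extdata/x11_affinity_panel.tsv`) the printed MM/PBSA and
pair-potential columns correlate with experimental ΔG at r = 0.63 and
r = 0.85 (p ≈ 0.03).

`run_screen(config)` drives the whole chain (template → pockets →
threading → scores → benchmark) from one JSON/list configuration and
writes scores, report, logs and a provenance record into a run directory.

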