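---
title: "Residue-level screening of PTB domain peptide specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-level screening of PTB domain peptide specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptbscreen)
```

## The model

PTB (phosphotyrosine-binding) domains recognize short peptides carrying an
NPXY/NXXY motif; the motif tyrosine — phosphorylated or not — anchors the
peptide in a groove, and residues flanking the motif modulate affinity.
`ptbscreen` implements a residue-level, structure-based scoring scheme for
ranking candidate peptides against one template complex:

1. **Pocket extraction.** From a peptide-bound structure, every
   (peptide residue, domain residue) pair whose minimum inter-atomic
   distance is strictly below a cutoff (default 4.5 Å, any atoms,
   hydrogens included when present) is a contact. Grouping contacts by
   peptide position — indexed with the motif tyrosine at 0 and N-terminal
   flanks negative, so "Tyr(−5)" reads naturally — gives a per-position
   *binding pocket*: the set of domain residues lining that position.
2. **Threading.** A candidate sequence is aligned to the template peptide
   by superposing motif tyrosines and extending position-by-position, with
   no gaps; overhangs are dropped and uncovered template positions simply
   contribute no terms. This is the residue-level analogue of rebuilding
   side chains on a fixed template backbone: the template's contact map is
   reused for every candidate rather than re-derived from a per-candidate
   atomic model (`score_panel()` exposes this as the default; a caller who
   does have full-atom models can recompute contacts per candidate and
   score those pockets instead).
3. **Phosphomimic.** Phosphotyrosine is not part of the 20-residue
   alphabet of contact potentials, so tyrosines are substituted by
   glutamate before scoring. The default mode mutates *every* tyrosine
   (`all_tyr`); `motif_only` restricts the substitution to the anchor
   tyrosine. Both are exposed because the two conventions differ in how
   aggressively they treat flanking tyrosines; `all_tyr` is the default
   since benchmark panels of phosphopeptides are typically mimicked
   wholesale.
4. **Scoring.** The binding score is the sum of contact-potential entries
   over all occupied pockets, `S = Σ_i Σ_{j∈pocket(i)} E(a_i, b_j)`, lower
   = more favorable. Only domain–peptide pairs are summed; intra-peptide
   contacts are excluded, matching the view of the score as an
   interaction energy.

Evaluation uses two routes. With measured dissociation constants,
`delta_g_from_kd()` converts Kd to free energy (ΔG = RT ln Kd,
R = 1.987204×10⁻³ kcal mol⁻¹ K⁻¹) and `pearson()` reports r with a
two-tailed p-value from the exact t distribution
(t = r√(n−2)/√(1−r²), df = n−2). With binary binder labels, `roc_curve()`
sweeps the prediction threshold over every observed score — a peptide is
predicted a binder when its score is *strictly below* the cutoff, so ties
at the threshold are predicted non-binders — and integrates the ROC by the
trapezoidal rule. That construction makes the AUC identical to the
tie-corrected Mann–Whitney statistic (half credit for cross-class ties),
which the tests verify by exhaustive pair counting.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `cutoff` (contacts) | 4.5 | Å | the any-atom contact criterion defining pockets; strict `<`, so a pair at exactly 4.5 Å is out |
| `da_cutoff` (H-bonds) | 3.5 | Å | N(donor)···O(acceptor) heavy-atom distance; no angle term, so the criterion also works on structures without hydrogens |
| `temperature` | 300 | K | Kd → ΔG conversion |
| `phosphomimic` | `all_tyr` | — | see above |
| identity clustering | 90 | % identity | redundancy threshold; global alignment, match +1 / mismatch 0 / gap −1, identity = matches / alignment columns |
| `fit` (RMSD) | `TRUE` | — | Kabsch superposition before RMSD; fitted RMSD is the standard reading for conformational comparisons |

Hydrogen-bond counts from pure distance criteria are qualitative: without
an angular term a short N···O pair that is geometrically incapable of
bonding is still reported, so the detector is an inventory tool, not an
energy model. Likewise the exact identity-computation conventions
(alignment scoring, denominator) vary between programs; the defaults here
are documented and configurable rather than claimed canonical.

## The synthetic-data generator

Because real benchmark inputs (peptide-bound crystal structures and
peptide-array panels) cannot be bundled, the generator produces desk-scale
stand-ins with *known* ground truth:

* `make_complex()` writes a two-chain PDB file in which each residue is a
  rigid five-atom cluster (N, CA, C, O, CB) and each designed
  (peptide, domain, distance) contact is realized exactly (±0.01 Å, solved
  by root-finding on the center separation), while all non-designed pairs
  stay beyond cutoff + 1 Å. Geometry is verified analytically before the
  file is emitted; unsatisfiable requests (distances below ~2 Å, more than
  four partners per peptide residue) error out. The returned ground-truth
  contact map is what `compute_contacts()` must recover from the text —
  the round-trip that pins down the parser and the distance code.
* `make_panel()` emulates a binder / non-binder peptide-array panel over a
  pocket map. Every sequence carries the motif in the template register
  (Asn at −3, the pY token at 0). Non-binders draw remaining positions
  uniformly from the 20 residues; binders draw pocket-contacting positions
  from a Boltzmann-like bias toward low pocket energy. The inverse
  temperature is solved (by `uniroot` on the closed-form expected energy)
  so that the *expected* binder/non-binder score separation equals
  `effect_size` in matrix units — the knob is the quantity you actually
  care about, not an opaque bias strength. `noise_sd` perturbs the
  sampling energies per binder, blurring the planted signal; synthetic
  affinities follow log Kd = slope·score + intercept + N(0, sd).

Defaults are fixed once as the study conditions: 69 binders / 54
non-binders (the size of the ShcA peptide-array panel), effect size 3,
noise 0.25, Kd coupling slope 1 / intercept −12 / sd 0.5 giving
micromolar-range affinities for typical scores. The acceptance analyses
use 100/100 panels so the AUC estimate has a standard error of ~0.02.

What passing these tests shows — and does not. The generator plants a
signal expressed *through the same pocket-sum score the pipeline
computes*, so recovery (AUC ≳ 0.9 at effect size 3, AUC ≈ 0.5 at effect
size 0) validates the mechanics of threading, mimicking, and scoring,
end-to-end and seed-reproducibly. It says nothing about whether a contact
potential captures real PTB energetics: real panels have correlated
positions, register shifts, and conformational effects the generator does
not emulate. On real data the published experience is sobering —
reasonable discrimination for one Shc-family domain (AUC ≈ 0.7) and
near-chance for another (≈ 0.56) when static crystal templates are used —
and reproducing those numbers needs the actual structures and panels,
which is out of scope here.

## Numerical choices and degenerate inputs

* Contacts use strict `<`; ties at the cutoff are excluded. Cutoff
  monotonicity (pairs(c₁) ⊆ pairs(c₂) for c₁ ≤ c₂) is property-tested.
* Kabsch superposition uses the SVD solution with the determinant
  correction, so reflections are never applied; fitted RMSD under any
  proper rigid motion is zero to 1e−8, verified also against a
  quaternion-parameterized numeric minimization.
* Multiple motif occurrences: a phosphorylated occurrence wins, then the
  leftmost — a deterministic, logged tie-break. Motif-less peptides are
  excluded and reported, never force-aligned.
* `pearson()` refuses n < 3 and zero-variance inputs; `roc_curve()` and
  `confusion_at()` refuse single-class inputs. Empty pocket maps score 0
  by the empty-sum convention.
* Cluster representatives are chosen deterministically (longest sequence,
  ties by id) so the 90%-identity reduction is reproducible; a seeded
  random pick is available to emulate randomized selection.
* All generator randomness flows from one integer seed per call; PDB text
  is byte-identical across runs with equal arguments.

## Problem sizes

The test-suite and acceptance analyses run on synthetic complexes of 4–13
peptide and 4–12 domain residues, panels of up to 200 peptides, and 100
seeded round-trip instances — sizes chosen so every check recomputes from
scratch in seconds while still exercising each code path at meaningful
multiplicity.

## Known limitations

* The packaged contact potential is a synthetic stand-in (see
  `synthetic_contact_matrix()`); screening conclusions about real peptides
  require a published potential supplied via `load_matrix()`.
* One template register per candidate: no multi-register scanning, no
  gaps, no side-chain geometry, no recomputed contacts per candidate in
  the default path.
* No mmCIF input, no trajectory parsing; the RMSD and H-bond tools operate
  on static conformations supplied by the caller.
* ΔG conversion assumes a single temperature; published affinity tables
  are sometimes internally inconsistent under any single T, in which case
  printed ΔG values should be used directly as inputs (as the packaged
  affinity panel does).
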