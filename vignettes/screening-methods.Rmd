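---
title: "Methods: interaction fingerprints, ligand-type classification and kinetic ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interaction fingerprints, ligand-type classification and kinetic ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(a2ascreen)
```

This vignette is the package's account of its own science: the models and
procedures, the parameters that matter, the design choices made where the
design was genuinely open, and what the synthetic tests do and do not show
about real screening data.

## The interaction fingerprint

A docked pose is reduced to one 8-bit block per binding-site residue:
hydrophobic contact (b0), aromatic face–face (b1) and edge–face (b2)
stacking, the residue acting as H-bond acceptor (b3) or donor (b4), a salt
bridge with the protein positively (b5) or negatively (b6) charged, and
coordination to a metal ion (b7). Bits are binary, not counts: a residue
either makes an interaction of a class or it does not.

The geometric cutoffs are not dictated by any single reference; the
defaults follow common interaction-fingerprint practice and are all
configurable through `interaction_criteria()`:

| criterion | default | unit |
|---|---|---|
| hydrophobic C/S–C/S contact | 4.0 | Å |
| H-bond heavy-atom distance | 3.5 | Å |
| H-bond D–H…A angle (only with explicit H) | ≥ 120 | degrees |
| salt bridge between charged-group centers | 4.0 | Å |
| ring centroid separation | 5.0 | Å |
| face–face normal angle | ≤ 30 | degrees |
| edge–face normal angle | 60–90 | degrees |
| metal coordination | 2.8 | Å |

Design notes, in the order the decisions came up:

* **Hydrogens.** Docked complexes routinely lack protein hydrogens and
  often ligand hydrogens too. Protein donors/acceptors therefore come from
  a residue template table; ligand donors require an attached explicit
  hydrogen only when the pose carries hydrogens at all, otherwise any N/O
  counts as a potential donor and the angle criterion is waived. This makes
  the detector monotone in its distance cutoffs (shrinking a cutoff can
  only clear bits), which is asserted as a property test.
* **Distinct donor and acceptor bits.** The residue's acceptor and donor
  roles are separate bits (b3/b4). The eight classes as listed in some
  descriptions repeat "acceptor" twice; we treat that as a transcription
  slip and keep the donor/acceptor pair distinct.
* **Waters.** Crystallographic waters are excluded from the residue list by
  default; `read_receptor(..., include_waters = TRUE)` retains them as
  single-oxygen residues that can accept H-bonds, for users who want
  water-mediated contacts to count.
* **Metals.** Metal ions appear in PDB files as HETATM records; they are
  kept as single-atom residues so bit b7 has something to bind to.
* **Feature matrix.** The column order is the union of residues contacted
  by any training pose, sorted by (receptor state, chain, residue number) —
  deterministic across runs. Poses are rows; each pose is one classified
  sample, and the pose's docking score is appended as one extra numeric
  column. Per-receptor-state pose sets are stacked row-wise, with the
  grouped cross-validation (below) guarding against leakage between poses
  of the same molecule.

## Chemical fingerprints and novelty

`ecfp4()` computes a hashed circular fingerprint in the ECFP4 configuration
(radius 2, 4096 bits, binary). Atom invariants are (atomic number, heavy
degree, implicit-H count, formal charge, ring membership); neighborhoods
are hashed iteratively with sorted (bond order, neighbor id) pairs, so the
result is independent of input atom order, and SMILES are canonicalized via
Open Babel before parsing as a second guard. The implementation is
self-contained because no installed R package provides hashed Morgan
fingerprints at this configuration; it follows the standard construction
but is not bit-compatible with other toolkits — all similarity statements
in the package are internally consistent, which is what clustering and
novelty need.

Novelty of a candidate is its maximum Tanimoto similarity to a user-supplied
reference set; `novel` means strictly below the threshold (default 0.4).
Reproducing any published per-compound Tc against a specific database
release would require that exact release and is out of scope.

## Ligand-type classification

Random forests (default 500 trees, default hyperparameters — deliberately
no tuning) are trained on pose-level samples with molecule-level labels.
The probability of a molecule being an antagonist is the fraction of trees
voting "antagonist", averaged over all available poses of the molecule
(arithmetic mean; "average probability" admits other readings, and the
aggregation is configurable in code by calling `predict()` per pose).

**Grouped stratified cross-validation.** Folds are built over molecules,
not poses: a greedy allocator assigns whole molecules (largest first) to
the fold where they least increase the squared deviation of the fold's
per-class counts from the ideal n/k targets. Two properties are asserted on
every run: no molecule appears on both sides of any split, and per-fold
class counts stay within one molecule's worth of the target — the best any
group-preserving assignment can guarantee. On tiny instances the greedy
result is compared against exhaustive enumeration of all assignments.

**Metrics.** Precision, recall, F1 and accuracy are computed from the
confusion matrix at a 0.5 score threshold; ROC AUC by trapezoidal
integration over score thresholds. Zero-denominator metrics are reported as
0 with a warning so CV tables stay numeric. Tests cross-check everything
against naive loop implementations and the Mann–Whitney formulation of AUC.

**Attribution.** `shap_attributions()` implements the path-dependent
TreeSHAP recursion directly on the forest's trees, with node covers
obtained by routing each tree's in-bag samples through it. Local accuracy —
base value plus the attribution sum equals the predicted probability — is
exact up to floating point and asserted at 1e-6 for every explained sample;
on small trees the values are checked against exhaustive Shapley coalition
enumeration. Attribution cost grows with tree size and sample count
(O(leaves × depth²) per sample and tree), so global summaries are best
computed on a representative sample subset.

**Filters.** Both decision gates are boundary-inclusive: probability ≥ 0.84
and pKd ≥ 5.5 survive. The affinity cutoff uses the exact conversion
(pKd 5.5 ↔ Kd = 10^-5.5 M ≈ 3.16 µM); descriptions equating pKd 5.5 with
10 µM conflate it with pKd 5.0, and the cutoff is exposed as configuration
for anyone who prefers the looser reading.

## Diversity clustering

Clustering operates on the raw 1 − Tanimoto distance matrix with
average-linkage agglomeration — average linkage because Tanimoto distances
on sparse fingerprints are noisy and single/complete linkage over- and
under-merge respectively; the linkage is an argument. The number of
clusters maximizes the mean silhouette width computed *on the original
distances*, not on any embedding (the distances are the primary object;
an option to cluster on the PCA embedding exists for comparison), with
ties resolved toward fewer clusters. PCA (50 components) is used only en
route to the 2-D t-SNE inspection map (perplexity 30, learning rate 200,
5000 iterations by default; exact quadratic-time gradient, adequate for the
few hundred molecules that survive the filters). The map is for human
inspection only — no decision consumes t-SNE coordinates.

The published workflow picked final molecules from clusters by visual
inspection. The automated proxy is the cluster medoid (minimum summed
intra-cluster distance, ties by id order), and `render_report()` exports an
inspection sheet so a human can still override.

## The cAMP cascade

Affinity enters as equilibrium occupancy: a ligand at concentration L with
dissociation constant Kd occupies L/(L + Kd) of receptors; with a competing
reference agonist the standard two-ligand competition formulas apply.
Binding is treated at quasi-equilibrium throughout — occupancy is held
constant during each simulation, because the downstream question is the
steady signaling response, not binding kinetics.

The cascade itself is a minimal mass-action Gs branch:

$$\frac{d[G^*]}{dt} = k_{act} R_{occ} [G] - k_{hyd} [G^*], \qquad
\frac{d[cAMP]}{dt} = k_{basal} + k_{cat} [G^*][ATP] - k_{PDE} [cAMP]$$

with \([G] = G_{tot} - [G^*]\), optional ATP depletion
\(d[ATP]/dt = -k_{cat}[G^*][ATP]\), and \(k_{basal} = k_{PDE} \cdot
cAMP_{basal}\) so that zero occupancy is a fixed point at the basal cAMP
level. Full signal-transduction models of this pathway carry many more
species; this four-species reduction keeps the structure that matters for
*ranking* ligands — monotone occupancy-to-response coupling, saturation,
competitive antagonism — while every rate constant stays exposed in
`cascade_parameters()`. The defaults (2 µM receptor, 10 µM G protein, 5 mM
ATP, rates of order 0.1–1 s⁻¹ and 10⁻⁴ µM⁻¹s⁻¹) are placeholders chosen to
give clean dynamic range over the 10⁻³–10³ µM dose grid within a 300 s
window; they are not fits to receptor-specific data, and absolute cAMP
values are therefore not meaningful — only curve structure is. That is why
the validation surface is structural: analytic agreement in the linear
(no-depletion) regime to 0.1%, step-refinement stability to 0.1%,
mode-dependent monotonicity across random parameter draws, and the
hundredfold x50 shift between ligands of pKd 6 and 8.

Numerical choices: stiff-capable `lsoda` integration at rtol 1e-8 under a
user-facing grid of output steps (default 1000 over the window — the
step-halving invariant makes the output-grid interpretation immaterial);
the antagonist mode requires an explicit agonist tone, defaulting to a
pKd 7 reference agonist at its EC80 (4 × Kd); dose grids default to 24
log-spaced points between the stated bounds. Hill fits run on log-midpoint
parameterization via Levenberg–Marquardt with analytic-free residuals;
flat curves are flagged degenerate rather than fitted, and midpoints
outside the dose grid are flagged unreliable.

## The screening funnel

Stages run in a fixed order — top docking fraction (ceiling of fraction × n,
ties at the cut broken by molecule id), probability filter, affinity gate,
clustering with medoid selection, dose–response simulation, novelty
annotation, ranking by (probability, x50) — and every molecule records the
last stage it reached, so the funnel is auditable and provably monotone.
All stochastic steps are seeded; reruns reproduce reports bit-exactly. An
empty funnel is a warning (exit status 2 in the CLI), not an error: the
report is still written.

## What the synthetic data shows — and what it does not

The generators emulate the *structure* of a real campaign: molecules with
five poses against three receptor states; agonist-class rows enriched in
ribose-like H-bond marker bits (HIS278/SER277/THR88-style contacts) and
antagonist rows in hydrophobic anchor bits, with a configurable overlap
fraction (default 0.3) and shared anchor interactions; docking scores drawn
per class and state with agonists scoring better against the active state,
calibrated so the score feature alone supports only ~0.75 accuracy and the
classifier must also exploit the interaction bits. Pose bits vary around a
molecule-level tendency, so grouping matters. Synthetic "ECFP-style"
fingerprints are sampled bit vectors, not real molecules; a small set of
real SMILES (xanthines, adenosine analogues, controls) exercises the
fingerprint code on genuine chemical graphs.

Sizes used by the default test and acceptance runs — 50 molecules per class
× 15 poses for classification, 100 pocket fixtures, 20 planted-partition
instances, 20 Hill refits, 50 cascade parameter draws — were chosen to make
the property checks statistically meaningful at desk scale.

Passing these tests shows the machinery is correct: predicates match
independent brute-force oracles, folds never leak, attributions are exactly
additive, clustering recovers planted structure, the cascade obeys its
closed forms. It does not show that real A2A docking poses are this
separable, that the default geometric cutoffs are optimal for any given
docking program, or that the cascade's placeholder constants predict
measured cAMP — those require real structures, real libraries and
experimental calibration.

## Known limitations

* ECFP bits are not cross-toolkit comparable (internal consistency only).
* TreeSHAP in pure R is practical for hundreds, not millions, of
  (sample × tree) evaluations.
* The cascade omits β-arrestin, GRK and Ca²⁺ branches and all
  pharmacokinetics; rate constants are not fitted to receptor data.
* Exact t-SNE is O(n²) per iteration — fine for post-filter candidate sets,
  not for full screening libraries.
* The probability aggregation treats all poses equally; best-pose or
  median aggregation may suit other docking setups.
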