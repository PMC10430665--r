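# a2ascreen

Structure-based antagonist triage for the adenosine A2A receptor — and, by
construction, for any GPCR screened the same way.

## The problem

Virtual screening against a GPCR returns thousands of docked poses ranked by
a docking score, but the score alone says little about *how* a ligand will
act: an agonist and an antagonist can dock equally well while doing opposite
things to the cell. For the adenosine A2A receptor (a Parkinson's disease
and oncology target) the distinction is geometric: agonists reach deep into
the orthosteric pocket and hydrogen-bond through their ribose-like moiety to
residues on helices 3 and 7 (THR88, SER277, HIS278), while antagonists
anchor on the extracellular side (PHE168 stacking, GLU169 salt bridge)
without engaging the activation switch.

`a2ascreen` turns that observation into a decision pipeline:

1. **PLIF** — for every docked pose, a per-residue 8-bit protein–ligand
   interaction fingerprint: hydrophobic contact, aromatic face–face and
   edge–face stacking, H-bond acceptor/donor, salt bridge (protein positive
   or negative), and metal coordination; the docking score is appended as
   one extra feature.
2. **Classifier** — random forests trained on labeled agonist/antagonist
   libraries (PLIF-based and, in parallel, chemistry-based on hashed
   circular ECFP4 fingerprints, radius 2 / 4096 bits). Cross-validation is
   *grouped and stratified*: all poses of a molecule stay on one side of
   every split, so pose-level leakage cannot inflate the metrics.
   TreeSHAP attributions explain each prediction feature by feature, with
   `base + sum(attributions) = predicted probability` holding exactly.
3. **Filters** — candidates must reach an antagonist probability of at
   least 0.84 and a predicted pKd of at least 5.5 (Kd ≈ 3.16 µM).
4. **Diversity** — survivors are clustered on 1 − Tanimoto distances of
   their ECFP4 fingerprints (average-linkage hierarchical clustering, the
   number of clusters chosen by silhouette score); each cluster contributes
   its medoid as representative. A t-SNE map (via PCA to 50 components) is
   produced for visual inspection.
5. **Kinetic ranking** — each representative's pKd is converted to
   equilibrium receptor occupancy, L/(L + Kd), and fed into a mass-action
   Gs → adenylyl-cyclase → cAMP cascade simulated over a 10⁻³–10³ µM dose
   grid (2 µM receptor). The resulting dose–response curve is summarized by
   a four-parameter Hill fit, and candidates are ranked by probability and
   potency (x50).
6. **Novelty** — the maximum Tanimoto similarity to a reference set flags
   candidates whose chemotype is new (max Tc < 0.4).

A synthetic-data module generates pocket geometries that trigger chosen
interaction bits exactly, two-class ligand libraries with class-dependent
fingerprints and docking scores, and planted fingerprint partitions — so
every stage is testable without any external download.

## Worked example

Train and cross-validate the PLIF classifier on the synthetic two-class
library (50 molecules per class, 5 poses × 3 receptor states each), then run
the full screening funnel on the same molecules with class-independent
screening scores:

```r
library(a2ascreen)

lib <- make_labeled_library(library_spec(seed = 1))
cv <- cross_validate(lib$plif, lib$pose_labels, lib$groups,
                     k = 5, trees = 500, seed = 1)
print(cv)
#> <cv_report> 5-fold grouped CV
#>  fold precision recall    f1 accuracy   auc
#>     1     0.855  0.987 0.916    0.910 0.981
#>     2     0.986  0.920 0.952    0.953 0.995
#>     3     0.993  0.940 0.966    0.967 0.999
#>     4     0.993  1.000 0.997    0.997 1.000
#>     5     0.993  0.960 0.976    0.977 0.998
#> mean: precision=0.964 recall=0.961 f1=0.961 accuracy=0.961 auc=0.995
```

Accuracy stays above 0.9 even though no molecule's poses ever straddle a
fold boundary. The funnel then thins the candidate set stage by stage:

```r
set.seed(1)
model <- train_rf(lib$plif, lib$pose_labels, trees = 300, seed = 2)
mols <- data.frame(id = lib$molecule_ids,
                   best_score = rnorm(length(lib$molecule_ids), -7, 1),
                   pKd = runif(length(lib$molecule_ids), 4.8, 8))
res <- run_pipeline(mols, list(features = lib$plif, molecule_id = lib$groups),
                    model, pipeline_config(top_fraction = 0.5, k_range = 2:6,
                                           sim_n_steps = 200),
                    fingerprints = lib$ecfp)
print(res)
#> <pipeline_result>
#>   funnel: scored=100 -> top_fraction=50 -> prob_pass=24 -> affinity_pass=21 -> clustered=21 -> simulated=2
#>   final candidates:
#>  molecule_id probability   pKd  x50_uM novelty_tc rank
#>       ant036      0.9589 7.811  0.9247         NA    1
#>       ant019      0.9549 6.566 16.2604         NA    2
```

Reading the funnel: 100 scored molecules → top 50 by docking score → 24 with
antagonist probability ≥ 0.84 → 21 with pKd ≥ 5.5 → clustered into 2
chemotype families → 2 medoid representatives simulated. Both finalists are
true antagonists; the rank-1 candidate's simulated half-maximal dose
(x50 ≈ 0.92 µM) reflects its higher predicted affinity (pKd 7.8 ↔ Kd 16 nM,
competing against the reference agonist tone).

Novelty scoring on real chemistry:

```r
nv <- novelty(example_smiles()[["adenosine"]],
              lapply(example_smiles()[c("caffeine", "theobromine", "adenine")], ecfp4))
print(nv)
#> <novelty> query: max Tc = 0.269 to adenine -> NOVEL (threshold 0.40)
```

A thin command-line front end over the same functions is installed at
`system.file("cli/a2ascreen.R", package = "a2ascreen")`, with subcommands
`fingerprint`, `train`, `classify`, `cluster`, `simulate`, `screen` and
`report`.

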