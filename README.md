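# kinobeadr

Chemoproteomic target deconvolution for kinase inhibitors. Kinobeads
competition-binding pulldowns measure, for every quantifiable protein in a
native lysate, how much a free test compound competes the protein away from
broad-spectrum kinase-inhibitor beads. `kinobeadr` turns MaxQuant-style
protein-group tables from such plates into apparent binding constants,
target calls, selectivity scores and probe nominations, and provides the
companion TMT phosphoproteomics regulation analysis. It is written for
chemical biologists and computational proteomics people analyzing
dose-resolved competition pulldowns, and it ships a ground-truthed
synthetic-data generator so the entire pipeline is testable without any
external data.

## The model

For protein *p* and compound concentration *c*, relative residual binding
(intensity over the median of the plate's DMSO vehicle controls) follows
the slope-1 one-site competition model

    r(c) = 1 / (1 + c / IC50),

so a single dose [I] with residual r inverts to `IC50 = [I] * r / (1 - r)`,
applied at the dose whose residual is closest to 0.5. Because the beads
deplete some proteins from the lysate, the assay IC50 is corrected by the
protein's depletion factor cf — the capture ratio of two consecutive
pulldowns of the same vehicle lysate, capped at 1:

    Kd_app = IC50 * cf,    pKd_app = -log10(Kd_app in mol/l).

Targets are called by a random-forest classifier trained on rule-annotated
pairs (>= 30% competition at the top dose, clearly above vehicle
variability, >= 2 unique peptides) at a strict probability cutoff of 0.935.
Selectivity uses CATDS: the engagement `e(c) = c / (c + Kd_app)` of the
target of interest divided by the summed engagement of all of the
compound's targets, evaluated at the most potent target's Kd (where its
engagement is exactly 0.5). Chemical-probe candidates require
`Kd_app < 1 µM` and `CATDS_most potent > 0.5`. Full dose-response data are
fitted with a bounded four-parameter log-logistic model. The phospho arm
normalizes TMT channels (total-sum to control, then row-wise), tests each
treatment against control with an S0-moderated two-sample statistic against
a pooled balanced-permutation null at 1% Benjamini-Hochberg FDR, intersects
consistently down-regulated sites across treatments, and checks the
central Ser-Phe sequence motif.

## Worked example

```r
library(kinobeadr)

# a small ground-truthed panel: 10 compounds x 200 proteins, two-dose design
truth <- simulate_truth(n_compounds = 10, n_proteins = 200, seed = 7)
plate <- simulate_plate(truth, design = "two_dose", noise = TRUE, seed = 8)
plate
#> experiment_set: 200 protein groups x 34 wells on 1 plate(s)

run <- run_two_dose_pipeline(plate, seed = 9)
subset(run$matrix, compound_id == "C004")
#>      compound_id protein_id     kd_app  pkd_app            flag is_target
#> 1237        C004      P0037 1204.40117 5.919229 above_assay_max      TRUE
#> 1255        C004      P0055  572.30754 6.242371              ok      TRUE
#> 1275        C004      P0075   39.70038 7.401205              ok      TRUE
#> 1336        C004      P0136 1691.81563 5.771647 above_assay_max      TRUE

kds <- target_kds(run$matrix, "C004")
catds_most_potent(kds)
#> CATDS_P0075 = 0.885 at c* = 39.7 nM (0.5 / 0.565)

nominate_probes(run$matrix)[5, ]
#>   compound_id best_target   kd_app catds_most_potent passes
#> 5        C004       P0075 39.70038         0.8851609   TRUE
```

Reading: compound C004 binds four proteins; the two weakest estimates
extrapolate beyond the 1 µM top dose and are flagged `above_assay_max`
(they are kept out of selectivity denominators). Its best target P0075 has
an apparent Kd of 39.7 nM; at that concentration P0075 is engaged exactly
half-maximally (numerator 0.5) while all targets together contribute 0.565,
giving a compound-centric selectivity of 0.885. With a submicromolar best
target and CATDS above 0.5, C004 passes the probe criteria.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end on synthetic
data and write their tables to `results/`:

1. `01_simulate.R` — generate the panel (20 compounds + 76-target reference
   compound x 1,500 proteins) and write the protein-group table + layout.
2. `02_affinity.R` — filter, normalize, estimate Kd_app, train/apply the
   target classifier, write the drug-target matrix.
3. `03_selectivity.R` — CATDS scores, probe nomination, landscape summary.
4. `04_qc.R` — reference-compound replicate concordance (FPR/FNR,
   sensitivity/specificity) and two-dose vs full-dose affinity concordance.
5. `05_phospho.R` — TMT phospho simulation, normalization, S0-moderated
   regulation tests, cross-condition intersection, Ser-Phe motif check.

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate.R`.

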