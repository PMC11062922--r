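#!/usr/bin/env Rscript
# Step 1: generate the synthetic compound panel this analysis runs on.
#
# A ground-truthed panel of 20 kinase inhibitors plus the promiscuous
# reference compound against 1500 pulldown-quantifiable proteins, plated in
# the two-dose competition design (100 nM / 1 uM, six DMSO controls, three
# reference replicates, one depletion pair). Writes the MaxQuant-style
# protein-group table, the plate layout, and the truth tables used by the
# later steps.

library(kinobeadr)

seed <- 1L
dir.create("results", showWarnings = FALSE)

truth <- simulate_truth(20, 1500, seed = seed)
es <- simulate_plate(truth, design = "two_dose", noise = TRUE,
                     seed = seed + 1L)

write_protein_groups(es, "results/protein_groups.txt")
write_plate_layout(es$layout, "results/plate_layout.tsv")
write.table(truth$targets, "results/truth_targets.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(truth$proteins[, c("protein_id", "cf", "annotation")],
            "results/truth_proteins.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Simulated", nrow(truth$proteins), "proteins x",
    nrow(truth$compounds), "compounds;",
    nrow(truth$targets), "true compound-protein interactions.\n")
cat("Plate has", nrow(es$layout), "wells (",
    sum(es$layout$role == "dmso_control"), "DMSO controls,",
    sum(es$layout$role == "reference_replicate"), "reference wells ).\n")
cat("Median true Kd:",
    round(median(truth$targets$kd), 1), "nM; median depletion cf:",
    round(median(truth$proteins$cf), 2), "\n")
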