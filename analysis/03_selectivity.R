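#!/usr/bin/env Rscript
# Step 3: selectivity scoring and chemical-probe nomination.
#
# Computes the compound-centric CATDS (evaluated at the most potent
# target's Kd, where its engagement is exactly half-maximal), nominates
# probe candidates (Kd_app < 1 uM and CATDS_most potent > 0.5), and
# summarizes the target landscape of the panel.

library(kinobeadr)

dtm <- read_affinity_matrix("results/drug_target_matrix.tsv")
dtm <- dtm[dtm$compound_id != "REFCMP", ]
truth_prot <- read.delim("results/truth_proteins.tsv")

categories <- categorize_binders(
  setNames(truth_prot$annotation, truth_prot$protein_id))
probes <- nominate_probes(dtm, categories = categories)
write.table(probes, "results/probe_candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE, na = "")

kinases <- truth_prot$protein_id[categories$category == "direct"]
land <- summarize_landscape(dtm, kinase_ids = kinases,
                            all_compounds = sprintf("C%03d", 1:20))
write.table(land$per_kinase_compound_counts,
            "results/per_kinase_compound_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sum(probes$passes), "of", nrow(probes),
    "compounds pass the probe criteria, covering",
    attr(probes, "n_kinases_targeted"), "direct-binder targets.\n")
print(land)
best <- probes[probes$passes, ]
best <- best[order(best$catds_most_potent, decreasing = TRUE), ]
if (nrow(best) > 0) {
  cat("Most selective passing compound:", best$compound_id[1],
      "( best target", best$best_target[1], ", Kd_app",
      round(best$kd_app[1], 1), "nM, CATDS",
      round(best$catds_most_potent[1], 3), ")\n")
}
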