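# In-code fixtures shared across the suite. Everything is generated, never
# stored: tiny hand-built plates for contract tests, simulated panels for
# property tests.

tiny_layout <- function(plate_id = "p1") {
  plate_layout(data.frame(
    plate_id = plate_id,
    well_id = c("D1", "D2", "D3", "C100", "C1000", "F1", "F2"),
    role = c("dmso_control", "dmso_control", "dmso_control",
             "compound", "compound", "depletion_first", "depletion_second"),
    compound_id = c(NA, NA, NA, "drugA", "drugA", NA, NA),
    concentration_nM = c(NA, NA, NA, 100, 1000, NA, NA),
    replicate = NA_integer_,
    stringsAsFactors = FALSE))
}

# experiment_set built directly from matrices (rownames = protein ids)
tiny_experiment <- function(intensity,
                            layout = tiny_layout(),
                            is_reverse = FALSE, is_contaminant = FALSE,
                            peptides = NULL, msms = NULL,
                            annotation = "protein kinase") {
  n <- nrow(intensity)
  prot <- data.frame(
    protein_id = rownames(intensity),
    gene_name = rownames(intensity),
    is_reverse = rep_len(is_reverse, n),
    is_contaminant = rep_len(is_contaminant, n),
    annotation = rep_len(annotation, n),
    stringsAsFactors = FALSE)
  if (is.null(peptides)) {
    peptides <- intensity
    peptides[] <- ifelse(is.na(intensity), 0, 5)
  }
  if (is.null(msms)) {
    msms <- intensity
    msms[] <- ifelse(is.na(intensity), 0, 10)
  }
  experiment_set(layout, prot, intensity, peptides, msms)
}

# write a protein-group file in the MaxQuant dialect from raw pieces
write_pg_fixture <- function(path, wells, intensity, peptides, msms,
                             reverse = NULL, contaminant = NULL) {
  n <- nrow(intensity)
  tab <- data.frame(`Protein IDs` = rownames(intensity),
                    `Gene names` = rownames(intensity),
                    check.names = FALSE, stringsAsFactors = FALSE)
  tab[["Reverse"]] <- if (is.null(reverse)) "" else ifelse(reverse, "+", "")
  tab[["Potential contaminant"]] <-
    if (is.null(contaminant)) "" else ifelse(contaminant, "+", "")
  for (w in wells) {
    tab[[paste0("Intensity ", w)]] <- intensity[, w]
    tab[[paste0("Unique peptides ", w)]] <- peptides[, w]
    tab[[paste0("MS/MS count ", w)]] <- msms[, w]
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
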