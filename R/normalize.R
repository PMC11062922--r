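#' Discard decoys, contaminants and vehicle-unquantified proteins
#'
#' Removes protein groups flagged as reverse (decoy) hits or potential
#' contaminants, and protein groups not quantified in any DMSO control well
#' of their plate. A protein quantified in a single vehicle well is retained.
#' Filtering is idempotent; the removal reasons are attached as the
#' `"removed"` attribute (protein id and reason).
#'
#' @param experiments an [experiment_set()].
#' @return the filtered [experiment_set()].
#' @export
filter_records <- function(experiments) {
  stopifnot(inherits(experiments, "experiment_set"))
  es <- experiments
  dmso_wells <- es$layout$well_id[es$layout$role == "dmso_control"]
  in_dmso <- rowSums(!is.na(es$intensity[, dmso_wells, drop = FALSE])) > 0

  reason <- rep(NA_character_, nrow(es$proteins))
  reason[!in_dmso] <- "not quantified in DMSO controls"
  reason[es$proteins$is_contaminant] <- "potential contaminant"
  reason[es$proteins$is_reverse] <- "reverse hit"
  keep <- is.na(reason)
  if (!any(keep)) {
    warning("all protein groups removed by filtering")
  }
  removed <- data.frame(protein_id = es$proteins$protein_id[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  out <- experiment_set(es$layout,
                        es$proteins[keep, , drop = FALSE],
                        es$intensity[keep, , drop = FALSE],
                        es$unique_peptides[keep, , drop = FALSE],
                        es$msms_count[keep, , drop = FALSE])
  attr(out, "removed") <- removed
  out
}

#' Convert raw intensities to relative residual binding
#'
#' For every protein and every competition well, the raw intensity is divided
#' by the median intensity of the same protein across the DMSO control wells
#' of the same plate, giving the relative residual binding r (1 = no
#' competition, 0 = complete competition). A competition well in which a
#' DMSO-quantified protein is missing is interpreted as complete competition
#' (r = 0) and flagged `imputed`, keeping label-free dropout at strong
#' competition auditable.
#'
#' The DMSO variability statistic `dmso_std` is the standard deviation of the
#' relative (post-normalization) DMSO intensities, so it is comparable across
#' proteins; `n_dmso_quantified` counts vehicle wells with a quantification.
#'
#' @param experiments a filtered [experiment_set()] (see [filter_records()]).
#' @return a list with class `residual_binding`:
#'   \describe{
#'     \item{profiles}{long data.frame: `plate_id`, `well_id`, `compound_id`,
#'       `replicate`, `concentration_nM`, `protein_id`, `r`, `imputed`.}
#'     \item{stats}{per (plate, protein): `dmso_median`, `dmso_std`,
#'       `n_dmso_quantified`, `max_unique_peptides`, `max_msms`.}
#'   }
#' @export
compute_residual_binding <- function(experiments) {
  stopifnot(inherits(experiments, "experiment_set"))
  es <- experiments
  profiles <- list()
  stat_rows <- list()
  for (pid in unique(es$layout$plate_id)) {
    lay <- es$layout[es$layout$plate_id == pid, ]
    dmso_wells <- lay$well_id[lay$role == "dmso_control"]
    comp_lay <- lay[lay$role %in% c("compound", "reference_replicate"), ]
    dmso <- es$intensity[, dmso_wells, drop = FALSE]
    dmso_median <- apply(dmso, 1, stats::median, na.rm = TRUE)
    n_dmso <- rowSums(!is.na(dmso))
    quantified <- n_dmso > 0
    rel_dmso <- dmso / dmso_median
    dmso_std <- apply(rel_dmso, 1, stats::sd, na.rm = TRUE)
    dmso_std[n_dmso == 1] <- 0
    all_wells <- lay$well_id
    stat_rows[[pid]] <- data.frame(
      plate_id = pid,
      protein_id = es$proteins$protein_id[quantified],
      dmso_median = dmso_median[quantified],
      dmso_std = dmso_std[quantified],
      n_dmso_quantified = n_dmso[quantified],
      max_unique_peptides =
        apply(es$unique_peptides[quantified, all_wells, drop = FALSE], 1, max),
      max_msms =
        apply(es$msms_count[quantified, all_wells, drop = FALSE], 1, max),
      stringsAsFactors = FALSE, row.names = NULL)
    for (i in seq_len(nrow(comp_lay))) {
      w <- comp_lay$well_id[i]
      iv <- es$intensity[quantified, w]
      r <- iv / dmso_median[quantified]
      imputed <- is.na(r)
      r[imputed] <- 0
      profiles[[paste(pid, w)]] <- data.frame(
        plate_id = pid,
        well_id = w,
        compound_id = comp_lay$compound_id[i],
        replicate = comp_lay$replicate[i],
        concentration_nM = comp_lay$concentration_nM[i],
        protein_id = es$proteins$protein_id[quantified],
        r = unname(r),
        imputed = unname(imputed),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  structure(list(profiles = do.call(rbind, c(profiles, make.row.names = FALSE)),
                 stats = do.call(rbind, c(stat_rows, make.row.names = FALSE))),
            class = "residual_binding")
}

#' @export
print.residual_binding <- function(x, ...) {
  cat("residual_binding:", nrow(x$stats), "plate-protein profiles,",
      nrow(x$profiles), "well measurements\n")
  invisible(x)
}
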