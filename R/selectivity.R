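#' Target engagement under the slope-1 one-site model
#'
#' Fraction of a target bound by the free compound at concentration c given
#' its apparent Kd, assuming a hill slope of one, top one and bottom zero:
#' engagement = c / (c + Kd).
#'
#' @param c concentration in nM (> 0).
#' @param kd apparent Kd in nM (> 0).
#' @return engagement fraction in (0, 1); vectorized.
#' @export
engagement <- function(c, kd) {
  if (any(c <= 0) || any(kd <= 0)) {
    stop("engagement needs positive concentration and Kd")
  }
  c / (c + kd)
}

#' Concentration- and target-dependent selectivity (CATDS)
#'
#' CATDS of a compound for a reference target (or paralog group) at an
#' evaluation concentration c* is the engagement of the reference divided by
#' the summed engagement of all of the compound's targets at c*. By default
#' c* is the Kd of the reference's most potent member, where that member's
#' engagement is exactly half-maximal. A score of one means all engagement
#' is concentrated on the reference.
#'
#' @param kds named numeric vector: the compound's full called-target set
#'   with apparent Kd in nM.
#' @param reference target id(s), or the name of an entry of `groups`.
#' @param cstar evaluation concentration in nM, or `"auto"` (Kd of the
#'   reference's most potent member).
#' @param groups named list of paralog groups (e.g.
#'   `list(CK2 = c("CSNK2A1", "CSNK2A2"))`) treated as one target of
#'   interest.
#' @return list with class `catds_result`: `reference`, `members`, `cstar`,
#'   `numerator`, `denominator`, `catds`.
#' @export
catds <- function(kds, reference, cstar = "auto", groups = list()) {
  if (length(kds) == 0) stop("empty target set")
  if (is.null(names(kds)) || any(!nzchar(names(kds)))) {
    stop("kds must be a named vector")
  }
  if (any(kds <= 0)) stop("all Kd values must be positive")
  ref_name <- reference
  if (length(reference) == 1 && reference %in% names(groups)) {
    members <- intersect(groups[[reference]], names(kds))
  } else {
    members <- reference
  }
  if (length(members) == 0 || !all(members %in% names(kds))) {
    stop("reference must be a subset of the compound's target set")
  }
  if (identical(cstar, "auto")) {
    cstar <- min(kds[members])
  }
  stopifnot(is.numeric(cstar), cstar > 0)
  num <- sum(engagement(cstar, kds[members]))
  den <- sum(engagement(cstar, kds))
  structure(list(reference = paste(ref_name, collapse = "+"),
                 members = members, cstar = cstar,
                 numerator = num, denominator = den,
                 catds = num / den),
            class = "catds_result")
}

#' Compound-centric selectivity at the most potent target
#'
#' CATDS evaluated at the Kd of the compound's most potent target: the
#' numerator is that target's half-maximal engagement (exactly 0.5), the
#' denominator sums all target engagements at that concentration. Ties on
#' the minimum Kd are broken toward the lexicographically first protein id.
#'
#' @inheritParams catds
#' @return a `catds_result` (see [catds()]).
#' @export
catds_most_potent <- function(kds) {
  if (length(kds) == 0) stop("empty target set")
  ord <- order(kds, names(kds))
  best <- names(kds)[ord[1]]
  catds(kds, best, cstar = unname(kds[best]))
}

#' @export
print.catds_result <- function(x, ...) {
  cat(sprintf("CATDS_%s = %.3f at c* = %.4g nM (%.3g / %.3g)\n",
              x$reference, x$catds, x$cstar, x$numerator, x$denominator))
  invisible(x)
}

#' Extract a compound's scoreable target Kd set from a call table
#'
#' @param matrix a drug-target long table (see [build_drug_target_matrix()]).
#' @param compound compound id.
#' @param include_unreliable include targets flagged `above_assay_max`
#'   (default FALSE: affinities beyond the top assayed dose are excluded
#'   from selectivity denominators).
#' @return named Kd vector (nM).
#' @export
target_kds <- function(matrix, compound, include_unreliable = FALSE) {
  rows <- matrix[matrix$compound_id == compound & matrix$is_target &
                   is.finite(matrix$kd_app), , drop = FALSE]
  if (!include_unreliable && "flag" %in% names(rows)) {
    rows <- rows[rows$flag == "ok", , drop = FALSE]
  }
  stats::setNames(rows$kd_app, rows$protein_id)
}

#' Nominate chemical-probe candidates
#'
#' A compound passes when its best (lowest-Kd) called target is sub-
#' micromolar (Kd_app < 1000 nM, strict) and its compound-centric
#' selectivity CATDS_most potent exceeds 0.5 (strict). The number of
#' distinct best-target proteins among passing compounds is attached as the
#' `"n_kinases_targeted"` attribute (restricted to direct binders when
#' `categories` is given).
#'
#' @param matrix drug-target long table ([build_drug_target_matrix()]).
#' @param kd_max affinity criterion in nM (default 1000).
#' @param catds_min selectivity criterion (default 0.5).
#' @param include_unreliable see [target_kds()].
#' @param categories optional [categorize_binders()] table used to restrict
#'   the targeted-kinase count to direct binders.
#' @return data.frame: compound_id, best_target, kd_app, catds_most_potent,
#'   passes.
#' @export
nominate_probes <- function(matrix, kd_max = 1000, catds_min = 0.5,
                            include_unreliable = FALSE, categories = NULL) {
  compounds <- unique(matrix$compound_id)
  rows <- lapply(compounds, function(cmp) {
    kds <- target_kds(matrix, cmp, include_unreliable)
    if (length(kds) == 0) {
      return(data.frame(compound_id = cmp, best_target = NA_character_,
                        kd_app = NA_real_, catds_most_potent = NA_real_,
                        passes = FALSE, stringsAsFactors = FALSE))
    }
    sc <- catds_most_potent(kds)
    data.frame(compound_id = cmp, best_target = sc$members,
               kd_app = unname(kds[sc$members]),
               catds_most_potent = sc$catds,
               passes = unname(kds[sc$members]) < kd_max & sc$catds > catds_min,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  best <- out$best_target[out$passes]
  if (!is.null(categories)) {
    direct <- categories$protein_id[categories$category == "direct"]
    best <- intersect(best, direct)
  }
  attr(out, "n_kinases_targeted") <- length(unique(best))
  out
}

#' Summarize the target landscape of a compound panel
#'
#' Resource-level counts over a drug-target call table: how many proteins
#' (optionally restricted to a kinase id set) are hit by at least one
#' compound, how many with submicromolar affinity, how many submicromolar
#' compound-target pairs exist, how many compounds have no (submicromolar)
#' target, and the per-protein compound counts.
#'
#' @param matrix drug-target long table.
#' @param kinase_ids optional protein ids to restrict protein-side counts.
#' @param all_compounds optional full compound id set (to count compounds
#'   with zero targets); defaults to the compounds present in `matrix`.
#' @return list with class `landscape_summary`.
#' @export
summarize_landscape <- function(matrix, kinase_ids = NULL,
                                all_compounds = NULL) {
  called <- matrix[matrix$is_target & is.finite(matrix$kd_app), , drop = FALSE]
  if (is.null(all_compounds)) all_compounds <- unique(matrix$compound_id)
  prot <- called
  if (!is.null(kinase_ids)) {
    prot <- prot[prot$protein_id %in% kinase_ids, , drop = FALSE]
  }
  sub <- prot[prot$kd_app < 1000, , drop = FALSE]
  per_kinase <- if (nrow(prot) > 0) {
    as.data.frame(table(protein_id = prot$protein_id),
                  responseName = "n_compounds", stringsAsFactors = FALSE)
  } else {
    data.frame(protein_id = character(), n_compounds = integer())
  }
  with_target <- unique(called$compound_id)
  with_sub <- unique(called$compound_id[called$kd_app < 1000])
  structure(list(
    n_kinases_targeted = length(unique(prot$protein_id)),
    n_kinases_submicromolar = length(unique(sub$protein_id)),
    n_pairs_submicromolar = nrow(sub),
    n_compounds_no_target = length(setdiff(all_compounds, with_target)),
    n_compounds_no_submicromolar = length(setdiff(all_compounds, with_sub)),
    per_kinase_compound_counts = per_kinase),
    class = "landscape_summary")
}

#' @export
print.landscape_summary <- function(x, ...) {
  cat("target landscape:\n",
      " proteins targeted by >=1 compound: ", x$n_kinases_targeted, "\n",
      " proteins with >=1 submicromolar compound: ",
      x$n_kinases_submicromolar, "\n",
      " submicromolar compound-protein pairs: ", x$n_pairs_submicromolar, "\n",
      " compounds with no target: ", x$n_compounds_no_target, "\n",
      " compounds with no submicromolar target: ",
      x$n_compounds_no_submicromolar, "\n", sep = "")
  invisible(x)
}
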