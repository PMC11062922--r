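#' Replicate-based assay performance metrics
#'
#' Compares per-replicate target calls of a reference compound against its
#' known target set within an assayed protein universe. Pooled
#' (micro-averaged) rates are primary:
#'
#'   FNR = missed reference detections / (replicates * |reference|)
#'   FPR = spurious calls / (replicates * |universe - reference|)
#'
#' with sensitivity = 1 - FNR and specificity = 1 - FPR. Per-replicate
#' (macro) rates are reported alongside.
#'
#' @param reference_targets protein ids the reference compound is known to
#'   hit in the assay.
#' @param replicate_calls list of character vectors, one per replicate
#'   pulldown, with the called target ids.
#' @param assayed_universe all protein ids quantifiable in the experiment
#'   (e.g. everything surviving DMSO filtering).
#' @return list with class `concordance_report`: the four pooled metrics,
#'   `n_reference_targets`, `n_replicates` and a `per_replicate` data.frame.
#' @export
replicate_concordance <- function(reference_targets, replicate_calls,
                                  assayed_universe) {
  reference_targets <- unique(reference_targets)
  assayed_universe <- unique(assayed_universe)
  if (length(assayed_universe) == 0 || length(reference_targets) == 0) {
    stop("reference target set and assayed universe must be nonempty")
  }
  if (!all(reference_targets %in% assayed_universe)) {
    stop("reference targets must lie within the assayed universe")
  }
  nonref <- setdiff(assayed_universe, reference_targets)
  per <- lapply(seq_along(replicate_calls), function(i) {
    calls <- intersect(unique(replicate_calls[[i]]), assayed_universe)
    tp <- length(intersect(calls, reference_targets))
    fp <- length(intersect(calls, nonref))
    fn <- length(reference_targets) - tp
    data.frame(replicate = i, tp = tp, fp = fp, fn = fn,
               tn = length(nonref) - fp,
               sensitivity = tp / length(reference_targets),
               specificity = 1 - fp / length(nonref))
  })
  per <- do.call(rbind, per)
  R <- length(replicate_calls)
  fnr <- sum(per$fn) / (R * length(reference_targets))
  fpr <- sum(per$fp) / (R * length(nonref))
  structure(list(n_reference_targets = length(reference_targets),
                 n_replicates = R,
                 false_negative_rate = fnr,
                 false_positive_rate = fpr,
                 sensitivity = 1 - fnr,
                 specificity = 1 - fpr,
                 per_replicate = per),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(paste0("assay concordance over %d replicate(s), %d reference",
                     " targets:\n FNR %.2f%%  FPR %.2f%%  sensitivity %.1f%%",
                     "  specificity %.1f%%\n"),
              x$n_replicates, x$n_reference_targets,
              100 * x$false_negative_rate, 100 * x$false_positive_rate,
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Cross-assay affinity concordance
#'
#' Pearson correlation between two sets of pKd estimates for the same
#' compound-protein pairs (e.g. two-dose versus full dose-response).
#'
#' @param pkd_a,pkd_b paired pKd vectors; incomplete pairs are dropped.
#' @return list: `r` (Pearson), `n`, `degenerate` (TRUE when either
#'   coordinate has zero variance, in which case `r` is `NA`), `pairs`.
#' @export
affinity_concordance <- function(pkd_a, pkd_b) {
  stopifnot(length(pkd_a) == length(pkd_b))
  ok <- is.finite(pkd_a) & is.finite(pkd_b)
  a <- pkd_a[ok]
  b <- pkd_b[ok]
  if (length(a) < 3) stop("need at least 3 complete pKd pairs")
  degenerate <- stats::sd(a) == 0 || stats::sd(b) == 0
  r <- if (degenerate) NA_real_ else stats::cor(a, b)
  list(r = r, n = length(a), degenerate = degenerate,
       pairs = data.frame(pkd_a = a, pkd_b = b))
}
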