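#' Estimate IC50 values from two-dose residual-binding profiles
#'
#' For each (compound, replicate, protein) the inhibitor concentration `[I]`
#' whose residual binding r is closest to 0.5 is selected (ties go to the
#' lower dose, the smaller extrapolation) and inverted under the slope-1
#' one-site competition model r(c) = 1 / (1 + c / IC50):
#'
#'   IC50 = \[I\] * r / (1 - r)
#'
#' with r clamped to \[epsilon, 1 - epsilon\]. Proteins whose residual
#' binding at the top dose is at or above `nonbinder_threshold` get no
#' affinity (flag `non_binder`, infinite IC50 sentinel); estimates with top
#' dose residual in (0.5, `nonbinder_threshold`) are kept but flagged
#' `above_assay_max` because affinities beyond the highest assayed dose are
#' extrapolations.
#'
#' @param residual_binding a [compute_residual_binding()] result.
#' @param doses the two assay concentrations in nM (default 100 and 1000).
#' @param epsilon clamp for r before inversion (default 1e-3).
#' @param nonbinder_threshold top-dose residual at or above which no affinity
#'   is reported (default 0.7, mirroring the 30 percent reduction rule).
#' @return data.frame with one row per (compound, replicate, protein):
#'   residual binding at both doses, `chosen_concentration`, `ic50` (nM) and
#'   `flag` in `ok`, `above_assay_max`, `non_binder`, `degenerate`.
#' @export
estimate_ic50_two_dose <- function(residual_binding,
                                   doses = c(100, 1000),
                                   epsilon = 1e-3,
                                   nonbinder_threshold = 0.7) {
  stopifnot(inherits(residual_binding, "residual_binding"))
  stopifnot(length(doses) == 2, all(doses > 0))
  doses <- sort(doses)
  prof <- residual_binding$profiles
  have <- unique(prof$concentration_nM)
  if (!all(doses %in% have)) {
    stop("profiles do not contain both doses ",
         paste(doses, collapse = " and "), " nM")
  }
  prof <- prof[prof$concentration_nM %in% doses, , drop = FALSE]
  lo <- prof[prof$concentration_nM == doses[1], ]
  hi <- prof[prof$concentration_nM == doses[2], ]
  kl <- paste(lo$plate_id, lo$compound_id,
              ifelse(is.na(lo$replicate), 0L, lo$replicate), lo$protein_id)
  kh <- paste(hi$plate_id, hi$compound_id,
              ifelse(is.na(hi$replicate), 0L, hi$replicate), hi$protein_id)
  m <- match(kl, kh)
  if (anyNA(m)) stop("unpaired dose wells in profiles")
  out <- data.frame(
    plate_id = lo$plate_id,
    compound_id = lo$compound_id,
    replicate = lo$replicate,
    protein_id = lo$protein_id,
    r_low = lo$r,
    r_high = hi$r[m],
    imputed_low = lo$imputed,
    imputed_high = hi$imputed[m],
    imputed = lo$imputed | hi$imputed[m],
    stringsAsFactors = FALSE)

  pick_low <- abs(out$r_low - 0.5) <= abs(out$r_high - 0.5)  # tie -> lower dose
  out$chosen_concentration <- ifelse(pick_low, doses[1], doses[2])
  r_chosen <- ifelse(pick_low, out$r_low, out$r_high)
  r_clamped <- pmin(pmax(r_chosen, epsilon), 1 - epsilon)
  out$ic50 <- out$chosen_concentration * r_clamped / (1 - r_clamped)

  out$flag <- "ok"
  out$flag[out$r_high > 0.5 & out$r_high < nonbinder_threshold] <- "above_assay_max"
  nb <- out$r_high >= nonbinder_threshold
  out$flag[nb] <- "non_binder"
  out$ic50[nb] <- Inf
  # a dropout-imputed top dose is inconsistent with the one-site model when
  # the low dose shows little competition: r_low >= 0.75 implies a top-dose
  # residual of at least r_low / (10 - 9 r_low) ~ 0.23, a signal that does
  # not genuinely vanish; such estimates are unreliable detection artifacts
  out$flag[out$imputed_high & !out$imputed_low & out$r_low >= 0.75] <-
    "degenerate"
  out$flag[is.na(out$r_low) | is.na(out$r_high)] <- "degenerate"
  out
}

#' Per-protein bead-depletion correction factors
#'
#' The correction factor cf is the fraction of a protein left uncaptured by
#' the beads, measured as the intensity ratio of two consecutive pulldowns of
#' the same vehicle lysate, capped at one. Per protein the median over all
#' available depletion pairs is used; proteins missing from either pulldown
#' of every pair get the global median cf as fallback (attached as the
#' `"global_median"` attribute).
#'
#' @param experiments an [experiment_set()] containing wells with roles
#'   `depletion_first` / `depletion_second` (paired in layout order per
#'   plate), or `NULL` when supplying raw vectors.
#' @param first,second alternatively, named intensity vectors of the first
#'   and second pulldown.
#' @return named numeric vector of cf in \[0, 1\] (`NA` where no depletion
#'   data; use the `"global_median"` attribute as fallback).
#' @export
compute_correction_factor <- function(experiments = NULL, first = NULL,
                                      second = NULL) {
  if (!is.null(experiments)) {
    stopifnot(inherits(experiments, "experiment_set"))
    lay <- experiments$layout
    ratios <- list()
    for (pid in unique(lay$plate_id)) {
      w1 <- lay$well_id[lay$plate_id == pid & lay$role == "depletion_first"]
      w2 <- lay$well_id[lay$plate_id == pid & lay$role == "depletion_second"]
      if (length(w1) != length(w2)) {
        stop("unpaired depletion wells on plate ", pid)
      }
      for (k in seq_along(w1)) {
        ratios[[paste(pid, k)]] <-
          pair_correction_factor(experiments$intensity[, w1[k]],
                                 experiments$intensity[, w2[k]])
      }
    }
    if (length(ratios) == 0) stop("no depletion pair wells in layout")
    mat <- do.call(cbind, ratios)
    cf <- apply(mat, 1, function(x) {
      if (all(is.na(x))) NA_real_ else stats::median(x, na.rm = TRUE)
    })
  } else {
    cf <- pair_correction_factor(first, second)
  }
  attr(cf, "global_median") <- stats::median(cf, na.rm = TRUE)
  cf
}

pair_correction_factor <- function(first, second) {
  stopifnot(length(first) == length(second))
  cf <- rep(NA_real_, length(first))
  names(cf) <- names(first)
  both <- !is.na(first) & !is.na(second)
  cf[both] <- pmin(1, second[both] / first[both])
  zero_first <- both & first == 0 & second > 0
  if (any(zero_first)) {
    warning("first pulldown intensity is zero for ", sum(zero_first),
            " protein(s); cf set to 1")
    cf[zero_first] <- 1
  }
  cf[is.nan(cf)] <- NA_real_
  cf
}

#' Convert IC50 estimates to apparent Kd
#'
#' Multiplies each IC50 by the protein's depletion correction factor:
#' Kd_app = IC50 * cf, so Kd_app <= IC50 always. pKd_app is the negative
#' decadic logarithm of Kd_app in mol/l. Sentinel (infinite) IC50s
#' propagate; proteins without depletion data fall back to the global median
#' cf.
#'
#' @param estimates data.frame from [estimate_ic50_two_dose()] (or any frame
#'   with `protein_id` and `ic50` columns).
#' @param cf named cf vector from [compute_correction_factor()].
#' @return `estimates` with `cf`, `kd_app` (nM) and `pkd_app` columns added.
#' @export
apply_depletion_correction <- function(estimates, cf) {
  fallback <- attr(cf, "global_median")
  if (is.null(fallback)) fallback <- stats::median(cf, na.rm = TRUE)
  cfv <- unname(cf[estimates$protein_id])
  cfv[is.na(cfv)] <- fallback
  estimates$cf <- cfv
  estimates$kd_app <- estimates$ic50 * cfv
  estimates$pkd_app <- ifelse(is.finite(estimates$kd_app) & estimates$kd_app > 0,
                              -log10(estimates$kd_app * 1e-9), NA_real_)
  estimates
}

#' Two-dose affinity pipeline step
#'
#' Convenience wrapper chaining [estimate_ic50_two_dose()] and
#' [apply_depletion_correction()].
#'
#' @inheritParams estimate_ic50_two_dose
#' @param cf named correction-factor vector.
#' @param ... passed to [estimate_ic50_two_dose()].
#' @return annotated estimate data.frame.
#' @export
two_dose_affinity <- function(residual_binding, cf, ...) {
  apply_depletion_correction(estimate_ic50_two_dose(residual_binding, ...), cf)
}
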