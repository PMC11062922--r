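#' Construct a TMT phosphosite table
#'
#' Holds reporter-ion intensities for phosphosites quantified across TMT
#' channels (treatments plus a vehicle control) in several biological
#' replicates, plus the +/-7-residue sequence window around each
#' phosphoacceptor.
#'
#' @param intensity 3-d numeric array site x channel x replicate with
#'   dimnames; `NA` marks missing values, all finite values must be >= 0.
#' @param windows named character vector of 15-residue sequence windows, one
#'   per site, phosphoacceptor central.
#' @param control name of the vehicle control channel (default `"DMSO"`).
#' @return list with class `phospho_table`.
#' @export
phospho_table <- function(intensity, windows = NULL, control = "DMSO") {
  stopifnot(is.array(intensity), length(dim(intensity)) == 3)
  dn <- dimnames(intensity)
  if (is.null(dn) || any(vapply(dn, is.null, TRUE))) {
    stop("intensity array needs full dimnames (site, channel, replicate)")
  }
  if (!control %in% dn[[2]]) {
    stop("control channel '", control, "' not among the channels")
  }
  if (any(intensity < 0, na.rm = TRUE)) stop("negative intensity")
  if (!is.null(windows)) {
    windows <- windows[dn[[1]]]
    if (anyNA(windows) || any(nchar(windows) != 15)) {
      stop("every site needs a 15-residue sequence window")
    }
  }
  structure(list(intensity = intensity, windows = windows, control = control),
            class = "phospho_table")
}

#' @export
print.phospho_table <- function(x, ...) {
  d <- dim(x$intensity)
  cat("phospho_table:", d[1], "sites x", d[2], "channels x", d[3],
      "replicates (control:", paste0(x$control, ")"), "\n")
  invisible(x)
}

#' Total-sum normalization of TMT channels
#'
#' Within each replicate, every channel is scaled so that its summed
#' intensity equals the control channel's sum, removing channel-loading
#' differences. Idempotent.
#'
#' @param table a [phospho_table()].
#' @param control control channel name (default: the table's).
#' @return the normalized `phospho_table`.
#' @export
total_sum_normalize <- function(table, control = NULL) {
  stopifnot(inherits(table, "phospho_table"))
  if (is.null(control)) control <- table$control
  x <- table$intensity
  for (j in seq_len(dim(x)[3])) {
    m <- base::matrix(x[, , j], dim(x)[1], dim(x)[2],
                      dimnames = dimnames(x)[1:2])
    sums <- colSums(m, na.rm = TRUE)
    if (any(sums == 0)) {
      stop("zero-sum channel in replicate ", dimnames(x)[[3]][j])
    }
    x[, , j] <- sweep(m, 2, sums[control] / sums, "*")
  }
  table$intensity <- x
  table
}

#' Row-wise normalization across replicates
#'
#' Per site, intensities are divided by the cross-replicate mean of the
#' per-replicate mean intensities, so that each site's mean of replicate
#' means equals one. Sites absent from all replicates are dropped with a
#' message. Idempotent.
#'
#' @param table a [phospho_table()].
#' @return the normalized `phospho_table`.
#' @export
row_wise_normalize <- function(table) {
  stopifnot(inherits(table, "phospho_table"))
  x <- table$intensity
  rep_means <- apply(x, c(1, 3), mean, na.rm = TRUE)   # site x replicate
  rep_means[is.nan(rep_means)] <- NA
  grand <- rowMeans(rep_means, na.rm = TRUE)
  empty <- !is.finite(grand) | grand == 0
  if (any(empty)) {
    message("dropping ", sum(empty), " site(s) absent from all replicates")
    x <- x[!empty, , , drop = FALSE]
    grand <- grand[!empty]
    if (!is.null(table$windows)) table$windows <- table$windows[!empty]
  }
  table$intensity <- sweep(x, 1, grand, "/")
  table
}

#' S0-moderated differential regulation test
#'
#' Tests each phosphosite for regulation in one treatment channel against
#' the vehicle control across biological replicates, on log2 intensities.
#' The statistic is a two-sample Student t with the SAM fudge factor S0
#' added to the standard-error term,
#'
#'   d = (mean(treated) - mean(control)) / (se_pooled + S0),
#'
#' which damps spuriously large statistics of low-variance sites. Sites
#' quantified in fewer than `min_replicates` replicates (both channels
#' present) are excluded. Significance: p-values for d are drawn from a null
#' distribution pooled across all tested sites and all balanced permutations
#' of the channel labels (the SAM mechanism; set `null = "t"` for plain
#' Student-t p-values), then Benjamini-Hochberg adjusted; a site is
#' significant at `q <= fdr`.
#'
#' @param table a normalized [phospho_table()].
#' @param condition treatment channel name.
#' @param control control channel name (default: the table's).
#' @param s0 fudge factor on the log2 scale (default 0.1; must be >= 0).
#' @param fdr FDR level (default 0.01).
#' @param min_replicates minimum complete replicates per site (default 3).
#' @param null `"permutation"` (pooled balanced label permutations) or
#'   `"t"` (t distribution with 2n-2 df).
#' @return data.frame: site_id, condition, n_replicates_detected, log2fc,
#'   stat, p, q, significant.
#' @export
test_regulation <- function(table, condition, control = NULL, s0 = 0.1,
                            fdr = 0.01, min_replicates = 3,
                            null = c("permutation", "t")) {
  stopifnot(inherits(table, "phospho_table"))
  null <- match.arg(null)
  if (s0 < 0) stop("s0 must be nonnegative")
  if (is.null(control)) control <- table$control
  x <- table$intensity
  cond <- log2(x[, condition, , drop = TRUE])
  ctrl <- log2(x[, control, , drop = TRUE])
  if (is.null(dim(cond))) {  # single site
    cond <- base::matrix(cond, 1); ctrl <- base::matrix(ctrl, 1)
  }
  complete <- is.finite(cond) & is.finite(ctrl)
  n_det <- rowSums(complete)
  tested <- which(n_det >= min_replicates)
  if (length(tested) == 0) stop("no site passes the replicate filter")

  s0_stat <- function(a, b) {
    n <- length(a)
    sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
    se <- sp * sqrt(2 / n)
    (mean(a) - mean(b)) / (se + s0)
  }
  obs <- numeric(length(tested))
  l2fc <- numeric(length(tested))
  nulls <- vector("list", length(tested))
  for (k in seq_along(tested)) {
    i <- tested[k]
    use <- complete[i, ]
    a <- cond[i, use]
    b <- ctrl[i, use]
    obs[k] <- s0_stat(a, b)
    l2fc[k] <- mean(a) - mean(b)
    if (null == "permutation") {
      nulls[[k]] <- balanced_perm_stats(a, b, s0_stat)
    }
  }
  if (null == "permutation") {
    pool <- sort(abs(unlist(nulls)))
    p <- (length(pool) - findInterval(abs(obs), pool) + 1) / (length(pool) + 1)
  } else {
    n <- n_det[tested]
    p <- 2 * stats::pt(-abs(obs), df = 2 * n - 2)
  }
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(site_id = dimnames(x)[[1]][tested],
                    condition = condition,
                    n_replicates_detected = n_det[tested],
                    log2fc = l2fc, stat = obs, p = p, q = q,
                    significant = q <= fdr,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

# Balanced relabelings of the pooled 2n values: pseudo-groups drawing
# floor(n/2) or ceil(n/2) members from the original condition group, so a
# true location shift (largely) cancels and the pooled null stays clean.
balanced_perm_stats <- function(a, b, stat_fn) {
  n <- length(a)
  pool <- c(a, b)
  k_set <- unique(c(floor(n / 2), ceiling(n / 2)))
  k_set <- setdiff(k_set, c(0, n))
  stats_out <- c()
  for (k in k_set) {
    ia <- utils::combn(n, k)            # from condition
    ib <- utils::combn(n, n - k)        # from control
    for (u in seq_len(ncol(ia))) {
      for (v in seq_len(ncol(ib))) {
        ga <- c(ia[, u], n + ib[, v])
        stats_out <- c(stats_out, stat_fn(pool[ga], pool[-ga]))
      }
    }
  }
  stats_out
}

#' Intersect consistently down-regulated sites across conditions
#'
#' Returns the sites significantly regulated with a negative log2 fold
#' change in every supplied condition.
#'
#' @param results list (length >= 2) of [test_regulation()] data.frames, or
#'   of plain character vectors of down-regulated site ids.
#' @return character vector of common site ids.
#' @export
intersect_conditions <- function(results) {
  if (length(results) < 2) stop("need at least 2 condition result sets")
  sets <- lapply(results, function(r) {
    if (is.character(r)) return(unique(r))
    r$site_id[r$significant & r$log2fc < 0]
  })
  Reduce(intersect, sets)
}

#' Check the central Ser-Phe substrate motif
#'
#' @param window 15-residue sequence window(s), phosphoacceptor central
#'   (position 8).
#' @return logical: TRUE when the central residue is serine and the +1
#'   residue is phenylalanine.
#' @export
motif_check <- function(window) {
  if (any(nchar(window) != 15)) {
    stop("sequence windows must be exactly 15 residues")
  }
  substr(window, 8, 8) == "S" & substr(window, 9, 9) == "F"
}

#' SAM-style percentile search for the fudge factor S0
#'
#' Scans candidate S0 values (percentiles of the per-site standard-error
#' distribution) and picks the one minimizing the coefficient of variation
#' of the median absolute statistic across standard-error bins, so that the
#' statistic's scale is independent of the site's variance.
#'
#' @param table a normalized [phospho_table()].
#' @param condition,control channel names.
#' @param min_replicates replicate filter as in [test_regulation()].
#' @param percentiles candidate percentiles of the se distribution.
#' @return the selected s0 value.
#' @export
estimate_s0 <- function(table, condition, control = NULL,
                        min_replicates = 3,
                        percentiles = seq(0, 1, by = 0.05)) {
  stopifnot(inherits(table, "phospho_table"))
  if (is.null(control)) control <- table$control
  x <- table$intensity
  cond <- log2(x[, condition, , drop = TRUE])
  ctrl <- log2(x[, control, , drop = TRUE])
  complete <- is.finite(cond) & is.finite(ctrl)
  tested <- which(rowSums(complete) >= min_replicates)
  diffm <- se <- numeric(length(tested))
  for (k in seq_along(tested)) {
    i <- tested[k]
    use <- complete[i, ]
    a <- cond[i, use]; b <- ctrl[i, use]
    sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
    se[k] <- sp * sqrt(2 / length(a))
    diffm[k] <- mean(a) - mean(b)
  }
  cand <- unique(stats::quantile(se, percentiles, names = FALSE))
  bins <- cut(se, stats::quantile(se, seq(0, 1, 0.1), names = FALSE),
              include.lowest = TRUE)
  cv <- vapply(cand, function(s0) {
    d <- abs(diffm) / (se + s0)
    med <- tapply(d, bins, stats::median)
    stats::sd(med, na.rm = TRUE) / mean(med, na.rm = TRUE)
  }, numeric(1))
  cand[which.min(cv)]
}
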