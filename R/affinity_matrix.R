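#' Build the compounds-by-proteins apparent affinity matrix
#'
#' Combines affinity estimates with classifier target calls into the long
#' drug-target table driving selectivity scoring and landscape summaries:
#' one row per called target with finite affinity, carrying Kd_app, pKd_app
#' and the reliability flag.
#'
#' @param estimates data.frame from [two_dose_affinity()] (or
#'   [full_dose_affinity()] with an `is_target` column merged in).
#' @param calls data.frame from [classify()] (matched by plate, compound,
#'   replicate and protein) or `NULL` to keep all finite estimates.
#' @return data.frame with class `drug_target_matrix`: `compound_id`,
#'   `protein_id`, `kd_app`, `pkd_app`, `flag`, `is_target`.
#' @export
build_drug_target_matrix <- function(estimates, calls = NULL) {
  out <- estimates
  if (!is.null(calls)) {
    key <- function(d) paste(d$plate_id, d$compound_id,
                             ifelse(is.na(d$replicate), 0L, d$replicate),
                             d$protein_id)
    m <- match(key(out), key(calls))
    if (anyNA(m)) stop("calls do not cover all estimates")
    out$is_target <- calls$is_target[m]
  } else if (is.null(out$is_target)) {
    out$is_target <- is.finite(out$kd_app)
  }
  reliable <- if (is.null(out$flag)) TRUE else out$flag != "degenerate"
  out <- out[out$is_target & is.finite(out$kd_app) & reliable,
             intersect(c("compound_id", "protein_id", "kd_app", "pkd_app",
                         "flag", "is_target"), names(out)),
             drop = FALSE]
  if (is.null(out$flag)) out$flag <- "ok"
  class(out) <- c("drug_target_matrix", "data.frame")
  out
}

#' Write / read a drug-target affinity matrix
#'
#' The matrix is stored wide: one row per compound, one column per protein,
#' cells holding Kd_app in nM and empty cells marking non-targets. The
#' reliability flags travel in a sidecar file `<path>.flags` (tab-delimited
#' compound, protein, flag) so that a write-then-read round trip is
#' lossless.
#'
#' @param matrix a `drug_target_matrix` (long form).
#' @param path output path for the wide matrix.
#' @export
write_affinity_matrix <- function(matrix, path) {
  if (nrow(matrix) == 0) stop("refusing to write an empty affinity matrix")
  compounds <- sort(unique(matrix$compound_id))
  proteins <- sort(unique(matrix$protein_id))
  wide <- base::matrix(NA_real_, length(compounds), length(proteins),
                       dimnames = list(compounds, proteins))
  wide[cbind(match(matrix$compound_id, compounds),
             match(matrix$protein_id, proteins))] <- matrix$kd_app
  out <- data.frame(compound_id = compounds, wide, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  flags <- matrix[, c("compound_id", "protein_id", "flag")]
  utils::write.table(flags, paste0(path, ".flags"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_affinity_matrix
#' @return [read_affinity_matrix()] returns the long `drug_target_matrix`.
#' @export
read_affinity_matrix <- function(path) {
  wide <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
  proteins <- setdiff(names(wide), "compound_id")
  rows <- list()
  for (p in proteins) {
    kd <- wide[[p]]
    hit <- !is.na(kd)
    if (!any(hit)) next
    rows[[p]] <- data.frame(compound_id = wide$compound_id[hit],
                            protein_id = p, kd_app = kd[hit],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out <- out[order(out$compound_id, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out$pkd_app <- -log10(out$kd_app * 1e-9)
  flag_path <- paste0(path, ".flags")
  if (file.exists(flag_path)) {
    fl <- utils::read.delim(flag_path, sep = "\t", stringsAsFactors = FALSE)
    m <- match(paste(out$compound_id, out$protein_id),
               paste(fl$compound_id, fl$protein_id))
    out$flag <- ifelse(is.na(m), "ok", fl$flag[m])
  } else {
    out$flag <- "ok"
  }
  out$is_target <- TRUE
  class(out) <- c("drug_target_matrix", "data.frame")
  out
}

#' Write / read a target-call table
#'
#' Delimited call table: compound, protein, probability, is_target and the
#' binder category when available.
#'
#' @param calls a [classify()] result (optionally with a `category` column).
#' @param path file path.
#' @export
write_target_calls <- function(calls, path) {
  cols <- intersect(c("plate_id", "compound_id", "replicate", "protein_id",
                      "probability", "is_target", "category"), names(calls))
  utils::write.table(calls[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_target_calls
#' @export
read_target_calls <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("", "NA"))
}
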