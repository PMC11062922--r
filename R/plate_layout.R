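#' Construct and validate a plate layout
#'
#' A plate layout maps each pulldown well of a (96-well) Kinobeads plate to
#' its experimental role. Competition wells carry a compound and a
#' concentration; vehicle wells carry DMSO only; reference-replicate wells
#' repeat a promiscuous control compound on every plate; the depletion pair
#' holds the two consecutive pulldowns of the same vehicle lysate used to
#' measure per-protein bead depletion.
#'
#' @param wells data.frame with columns `plate_id`, `well_id`, `role`,
#'   `compound_id`, `concentration_nM`, `replicate`. `role` must be one of
#'   `"compound"`, `"dmso_control"`, `"reference_replicate"`,
#'   `"depletion_first"`, `"depletion_second"`. `compound_id` and
#'   `concentration_nM` are `NA` for non-competition wells; `replicate`
#'   (integer) distinguishes reference-replicate pulldowns and is `NA`
#'   elsewhere.
#'
#' @return The validated data.frame with class `plate_layout`.
#' @export
plate_layout <- function(wells) {
  required <- c("plate_id", "well_id", "role", "compound_id",
                "concentration_nM", "replicate")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols) > 0) {
    stop("plate layout is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  wells <- as.data.frame(wells)[, required]
  wells$plate_id <- as.character(wells$plate_id)
  wells$well_id <- as.character(wells$well_id)
  wells$role <- as.character(wells$role)
  wells$compound_id <- as.character(wells$compound_id)
  wells$concentration_nM <- as.numeric(wells$concentration_nM)
  wells$replicate <- as.integer(wells$replicate)
  bad_role <- setdiff(unique(wells$role), plate_roles())
  if (length(bad_role) > 0) {
    stop("unknown well role(s): ", paste(bad_role, collapse = ", "))
  }
  for (pid in unique(wells$plate_id)) {
    pw <- wells[wells$plate_id == pid, ]
    if (anyDuplicated(pw$well_id)) {
      stop("duplicate well ids on plate ", pid)
    }
    if (!any(pw$role == "dmso_control")) {
      stop("plate ", pid, " has no DMSO control well")
    }
  }
  comp <- wells$role %in% c("compound", "reference_replicate")
  conc <- wells$concentration_nM[comp]
  if (anyNA(conc) || any(conc <= 0)) {
    stop("competition wells must have a positive concentration (nM)")
  }
  if (anyNA(wells$compound_id[comp])) {
    stop("competition wells must name a compound")
  }
  class(wells) <- c("plate_layout", "data.frame")
  wells
}

plate_roles <- function() {
  c("compound", "dmso_control", "reference_replicate",
    "depletion_first", "depletion_second")
}

#' Read or write a plate layout file
#'
#' Layouts are stored as plain tab-delimited tables with a header row and the
#' columns documented in [plate_layout()]. Empty cells become `NA`.
#'
#' @param path file path.
#' @return [read_plate_layout()] returns a `plate_layout`.
#' @export
read_plate_layout <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  plate_layout(tab)
}

#' @rdname read_plate_layout
#' @param layout a `plate_layout`.
#' @export
write_plate_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plate_layout"))
  utils::write.table(layout, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
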