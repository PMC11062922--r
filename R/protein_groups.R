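#' Bundle plate-structured pulldown quantifications
#'
#' An `experiment_set` holds per-protein label-free quantifications for every
#' well of one or more plates: raw intensities, unique-peptide counts and
#' MS/MS counts, together with the plate layout and the per-protein flags of
#' the search engine output.
#'
#' Intensities of zero in MaxQuant-style output mean "not quantified" and are
#' represented as `NA` throughout (never coerced back to zero during
#' analysis).
#'
#' @param layout a [plate_layout()].
#' @param proteins data.frame with columns `protein_id`, `gene_name`,
#'   `is_reverse`, `is_contaminant`, `annotation`.
#' @param intensity,unique_peptides,msms_count numeric/integer matrices with
#'   one row per protein (rownames = `protein_id`) and one column per layout
#'   well (colnames = `well_id`). `intensity` may contain `NA`; counts are
#'   nonnegative integers.
#'
#' @return list of the validated pieces with class `experiment_set`.
#' @export
experiment_set <- function(layout, proteins, intensity, unique_peptides,
                           msms_count) {
  stopifnot(inherits(layout, "plate_layout"))
  req <- c("protein_id", "gene_name", "is_reverse", "is_contaminant",
           "annotation")
  missing_cols <- setdiff(req, names(proteins))
  if (length(missing_cols) > 0) {
    stop("protein table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  proteins <- as.data.frame(proteins)
  if (anyDuplicated(proteins$protein_id)) {
    stop("duplicate protein group ids")
  }
  for (m in list(intensity, unique_peptides, msms_count)) {
    if (!identical(rownames(m), as.character(proteins$protein_id))) {
      stop("matrix rownames must equal the protein ids, in order")
    }
    if (!setequal(colnames(m), layout$well_id)) {
      stop("matrix columns must map one-to-one onto layout wells")
    }
  }
  if (any(intensity < 0, na.rm = TRUE)) stop("negative intensity")
  if (any(unique_peptides < 0, na.rm = TRUE) || any(msms_count < 0, na.rm = TRUE)) {
    stop("identification counts must be nonnegative")
  }
  ord <- as.character(layout$well_id)
  structure(
    list(layout = layout,
         proteins = proteins,
         intensity = intensity[, ord, drop = FALSE],
         unique_peptides = unique_peptides[, ord, drop = FALSE],
         msms_count = msms_count[, ord, drop = FALSE]),
    class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  cat("experiment_set:", nrow(x$proteins), "protein groups x",
      nrow(x$layout), "wells on",
      length(unique(x$layout$plate_id)), "plate(s)\n")
  invisible(x)
}

#' Read a MaxQuant-style protein-group table
#'
#' Parses a tab-delimited `proteinGroups.txt`-dialect table: a `Protein IDs`
#' column, optional `Gene names` and annotation columns, `Reverse` and
#' `Potential contaminant` marker columns (`"+"` convention), and per-well
#' columns `Intensity <well>`, `Unique peptides <well>` and
#' `MS/MS count <well>`. Zero intensities are treated as not quantified and
#' returned as `NA`. No rows are dropped at read time; decoy/contaminant
#' removal happens in [filter_records()].
#'
#' @param path file path to the tab-delimited table.
#' @param layout a [plate_layout()] whose `well_id`s name the per-well
#'   columns.
#' @return an [experiment_set()].
#' @export
read_protein_groups <- function(path, layout) {
  stopifnot(inherits(layout, "plate_layout"))
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!"Protein IDs" %in% names(tab)) {
    stop("no 'Protein IDs' column in ", path)
  }
  wells <- as.character(layout$well_id)
  for (w in wells) {
    for (prefix in c("Intensity ", "Unique peptides ", "MS/MS count ")) {
      if (!(paste0(prefix, w) %in% names(tab))) {
        stop("layout well '", w, "' has no '", prefix, w,
             "' column in the protein-group table")
      }
    }
  }
  grab <- function(prefix) {
    m <- sapply(wells, function(w) {
      col <- tab[[paste0(prefix, w)]]
      v <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(v) & !is.na(col) & col != "")
      if (length(bad) > 0) {
        stop("malformed numeric cell in column '", paste0(prefix, w),
             "', row ", bad[1], ": '", col[bad[1]], "'")
      }
      v
    })
    m <- matrix(m, nrow = nrow(tab), dimnames = list(NULL, wells))
    m
  }
  intensity <- grab("Intensity ")
  intensity[!is.na(intensity) & intensity == 0] <- NA  # zero = not quantified
  peps <- grab("Unique peptides ")
  peps[is.na(peps)] <- 0
  msms <- grab("MS/MS count ")
  msms[is.na(msms)] <- 0

  marker <- function(colname) {
    if (colname %in% names(tab)) {
      !is.na(tab[[colname]]) & tab[[colname]] == "+"
    } else {
      rep(FALSE, nrow(tab))
    }
  }
  proteins <- data.frame(
    protein_id = as.character(tab[["Protein IDs"]]),
    gene_name = if ("Gene names" %in% names(tab)) {
      as.character(tab[["Gene names"]])
    } else {
      as.character(tab[["Protein IDs"]])
    },
    is_reverse = marker("Reverse"),
    is_contaminant = marker("Potential contaminant"),
    annotation = if ("Annotation" %in% names(tab)) {
      as.character(tab[["Annotation"]])
    } else {
      ""
    },
    stringsAsFactors = FALSE)
  rownames(intensity) <- rownames(peps) <- rownames(msms) <- proteins$protein_id
  experiment_set(layout, proteins, intensity, peps, msms)
}

#' Write an experiment set back to the protein-group dialect
#'
#' Inverse of [read_protein_groups()]: `NA` intensities are written as 0
#' (not quantified), flags as `"+"` markers. A write-then-read round trip
#' reproduces the intensities and counts exactly.
#'
#' @param experiments an [experiment_set()].
#' @param path output file path.
#' @export
write_protein_groups <- function(experiments, path) {
  stopifnot(inherits(experiments, "experiment_set"))
  es <- experiments
  wells <- as.character(es$layout$well_id)
  out <- data.frame(`Protein IDs` = es$proteins$protein_id,
                    `Gene names` = es$proteins$gene_name,
                    Annotation = es$proteins$annotation,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out[["Reverse"]] <- ifelse(es$proteins$is_reverse, "+", "")
  out[["Potential contaminant"]] <- ifelse(es$proteins$is_contaminant, "+", "")
  for (w in wells) {
    iv <- es$intensity[, w]
    iv[is.na(iv)] <- 0
    out[[paste0("Intensity ", w)]] <- iv
    out[[paste0("Unique peptides ", w)]] <- es$unique_peptides[, w]
    out[[paste0("MS/MS count ", w)]] <- es$msms_count[, w]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
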