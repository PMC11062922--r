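#' Assemble the classifier feature table for target calling
#'
#' Joins two-dose residual binding with the per-protein DMSO statistics into
#' the fixed feature schema used by the rule annotator and the random-forest
#' classifier: residual binding at both doses, DMSO variability, DMSO median
#' intensity (log10), identification depth and the dropout-imputation flag.
#'
#' @param estimates data.frame from [estimate_ic50_two_dose()] (the residual
#'   binding columns are used).
#' @param residual_binding the matching [compute_residual_binding()] result
#'   (for the DMSO statistics).
#' @return data.frame: ids plus feature columns `r_low`, `r_high`,
#'   `dmso_std`, `log_dmso_median`, `max_unique_peptides`, `max_msms`,
#'   `imputed`.
#' @export
target_features <- function(estimates, residual_binding) {
  st <- residual_binding$stats
  m <- match(paste(estimates$plate_id, estimates$protein_id),
             paste(st$plate_id, st$protein_id))
  if (anyNA(m)) stop("estimates contain proteins without DMSO statistics")
  data.frame(
    plate_id = estimates$plate_id,
    compound_id = estimates$compound_id,
    replicate = estimates$replicate,
    protein_id = estimates$protein_id,
    r_low = estimates$r_low,
    r_high = estimates$r_high,
    dmso_std = st$dmso_std[m],
    log_dmso_median = log10(st$dmso_median[m]),
    max_unique_peptides = st$max_unique_peptides[m],
    max_msms = st$max_msms[m],
    imputed = as.numeric(estimates$imputed),
    stringsAsFactors = FALSE)
}

feature_schema <- function() {
  c("r_low", "r_high", "dmso_std", "log_dmso_median",
    "max_unique_peptides", "max_msms", "imputed")
}

#' Rule-based training-set annotation
#'
#' Labels a compound-protein pair `target` when the residual binding at the
#' top dose is reduced by at least 30 percent (r_high <= 0.7), the reduction
#' clearly exceeds the vehicle variability (1 - r_high >= k * dmso_std,
#' default k = 3), and the protein is identified with at least two unique
#' peptides. Pairs with r_high >= 0.9 are `non_target`; everything in
#' between is `ambiguous` and excluded from classifier training.
#'
#' @param features data.frame from [target_features()].
#' @param k multiple of the DMSO standard deviation the reduction must exceed
#'   (default 3).
#' @param max_residual top-dose residual at or below which a pair can be a
#'   target (default 0.7).
#' @param min_peptides minimum unique peptides (default 2).
#' @return character vector of labels in `target`, `non_target`, `ambiguous`.
#' @export
rule_annotate <- function(features, k = 3, max_residual = 0.7,
                          min_peptides = 2) {
  r <- features$r_high
  lab <- rep("ambiguous", nrow(features))
  lab[r <= max_residual &
        (1 - r) >= k * features$dmso_std &
        features$max_unique_peptides >= min_peptides] <- "target"
  lab[r >= 0.9] <- "non_target"
  lab
}

#' Train the random-forest target classifier
#'
#' Fits a seeded random forest on rule-labeled (or user-labeled) feature
#' vectors. Ambiguous labels are dropped. Defaults: 500 trees, square-root
#' feature subsampling. Out-of-bag accuracy and class counts are stored.
#'
#' @param features data.frame containing the [feature_schema()] columns.
#' @param labels character vector with `target` / `non_target` (and possibly
#'   `ambiguous`, which is excluded).
#' @param seed integer seed; retraining with the same seed reproduces
#'   identical predictions.
#' @param ntree,mtry forest hyperparameters.
#' @return list with class `target_classifier`.
#' @export
train_classifier <- function(features, labels, seed = 1L, ntree = 500,
                             mtry = NULL) {
  keep <- labels %in% c("target", "non_target")
  x <- features[keep, feature_schema(), drop = FALSE]
  y <- factor(labels[keep], levels = c("non_target", "target"))
  counts <- table(y)
  if (any(counts < 50)) {
    stop("need at least 50 examples per class; got ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  if (max(counts) / min(counts) > 50) {
    stop("class imbalance beyond 50:1; rebalance the simulation ",
         "(more targets or fewer background proteins)")
  }
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(x))))
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = ntree, mtry = mtry)
  oob <- 1 - mean(rf$predicted != y)
  structure(list(model = rf, features = feature_schema(), seed = seed,
                 ntree = ntree, mtry = mtry, class_counts = counts,
                 oob_accuracy = oob),
            class = "target_classifier")
}

#' @export
print.target_classifier <- function(x, ...) {
  cat("target_classifier: random forest,", x$ntree, "trees, OOB accuracy",
      sprintf("%.3f", x$oob_accuracy), "\n")
  invisible(x)
}

#' Score pairs and call targets at a fixed probability cutoff
#'
#' Applies the trained classifier and annotates a pair as target when its
#' probability is strictly greater than the cutoff (default 0.935).
#'
#' @param classifier a [train_classifier()] model.
#' @param features data.frame containing the [feature_schema()] columns.
#' @param threshold probability cutoff (strict inequality; default 0.935).
#' @return `features` with `probability` and `is_target` columns added.
#' @export
classify <- function(classifier, features, threshold = 0.935) {
  stopifnot(inherits(classifier, "target_classifier"))
  missing_cols <- setdiff(classifier$features, names(features))
  if (length(missing_cols) > 0) {
    stop("feature schema mismatch; missing: ",
         paste(missing_cols, collapse = ", "))
  }
  prob <- stats::predict(classifier$model,
                         newdata = features[, classifier$features,
                                            drop = FALSE],
                         type = "prob")[, "target"]
  features$probability <- unname(prob)
  features$is_target <- features$probability > threshold
  features
}

#' Choose the probability cutoff minimizing total miscalls
#'
#' Scans candidate cutoffs and returns the one minimizing the summed false
#' positives and false negatives on labeled validation data, the criterion
#' behind the 0.935 default.
#'
#' @param probability classifier probabilities.
#' @param truth logical ground truth (TRUE = target).
#' @return the selected cutoff.
#' @export
select_probability_cutoff <- function(probability, truth) {
  stopifnot(length(probability) == length(truth))
  cand <- sort(unique(c(0, probability, 1)))
  cost <- vapply(cand, function(th) {
    call <- probability > th
    sum(call & !truth) + sum(!call & truth)
  }, numeric(1))
  cand[which.min(cost)]
}

#' Keyword set defining direct Kinobeads binders
#'
#' Proteins whose functional annotation marks them as able to bind the
#' immobilized probes directly: kinases and other purine/cofactor binders.
#' All other called targets are assumed to be enriched as interaction
#' partners (indirect binders).
#'
#' @return character vector of annotation keywords.
#' @export
direct_binder_keywords <- function() {
  c("protein kinase", "lipid kinase", "nucleotide binder", "helicase",
    "ATPase", "GTPase", "FAD", "heme")
}

#' Categorize called targets as direct or indirect binders
#'
#' @param annotations named character vector: protein id -> annotation
#'   string.
#' @param keywords keyword set (default [direct_binder_keywords()]); matching
#'   is case-insensitive substring matching, and the category is invariant to
#'   the order of the keywords.
#' @return data.frame: `protein_id`, `category` (`direct` / `indirect`),
#'   `basis` (the matched keyword or "").
#' @export
categorize_binders <- function(annotations,
                               keywords = direct_binder_keywords()) {
  ann <- tolower(as.character(annotations))
  basis <- rep("", length(ann))
  for (kw in keywords) {
    hit <- basis == "" & grepl(tolower(kw), ann, fixed = TRUE)
    basis[hit] <- kw
  }
  data.frame(protein_id = names(annotations),
             category = ifelse(basis != "", "direct", "indirect"),
             basis = basis, stringsAsFactors = FALSE, row.names = NULL)
}
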