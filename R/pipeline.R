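#' Run the full two-dose affinity and target-calling pipeline
#'
#' Chains the per-plate stages: decoy/contaminant/vehicle filtering,
#' DMSO-median normalization to residual binding, two-dose IC50 estimation,
#' bead-depletion correction to apparent Kd, rule annotation, classifier
#' training (unless a trained classifier is supplied), probability scoring
#' and the assembly of the drug-target matrix.
#'
#' @param experiments an [experiment_set()] with depletion-pair wells.
#' @param classifier optional pre-trained [train_classifier()] model; if
#'   `NULL` one is trained on the rule-annotated pairs of this experiment.
#' @param threshold probability cutoff for target calls (default 0.935).
#' @param seed seed for classifier training.
#' @param train_max_ratio cap on the non-target:target ratio of the
#'   training subsample (default 20; panels quantify vastly more
#'   non-binders than binders, and the excess non-target examples add
#'   nothing but training time and imbalance).
#' @param ... passed to [estimate_ic50_two_dose()].
#' @return list: `experiments` (filtered), `residual_binding`, `cf`,
#'   `estimates`, `features`, `labels`, `classifier`, `calls`, `matrix`.
#' @export
run_two_dose_pipeline <- function(experiments, classifier = NULL,
                                  threshold = 0.935, seed = 1L,
                                  train_max_ratio = 20, ...) {
  filtered <- filter_records(experiments)
  rb <- compute_residual_binding(filtered)
  cf <- compute_correction_factor(filtered)
  estimates <- two_dose_affinity(rb, cf, ...)
  features <- target_features(estimates, rb)
  labels <- rule_annotate(features)
  if (is.null(classifier)) {
    idx_t <- which(labels == "target")
    idx_n <- which(labels == "non_target")
    set.seed(seed)
    if (length(idx_n) > train_max_ratio * length(idx_t)) {
      idx_n <- sample(idx_n, train_max_ratio * length(idx_t))
    }
    idx <- c(idx_t, idx_n)
    classifier <- train_classifier(features[idx, ], labels[idx], seed = seed)
  }
  calls <- classify(classifier, features, threshold = threshold)
  dtm <- build_drug_target_matrix(estimates, calls)
  list(experiments = filtered, residual_binding = rb, cf = cf,
       estimates = estimates, features = features, labels = labels,
       classifier = classifier, calls = calls, matrix = dtm)
}
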