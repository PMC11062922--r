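#' Simulate the ground truth of a compound-protein binding panel
#'
#' Draws the latent quantities every downstream stage is validated against:
#' per-protein baseline pulldown intensities (log-normal), bead-depletion
#' correction factors (Beta), functional annotations, and per-compound
#' target sets with apparent Kd values. Compound promiscuity is long-tailed
#' (negative binomial plus one): most compounds hit a handful of proteins,
#' a few hit dozens. Kds are log-uniform on \[1, 10000\] nM. One designated
#' promiscuous reference compound (modeled on a staurosporine-like control)
#' gets a fixed larger target count for replicate-concordance QC.
#'
#' @param n_compounds,n_proteins panel dimensions.
#' @param mean_targets mean number of targets per compound (default 5).
#' @param promiscuity_size negative-binomial size; smaller = longer tail
#'   (default 0.8).
#' @param n_reference_targets target count of the reference compound
#'   (default 76).
#' @param baseline_median,baseline_sdlog log-normal baseline intensity
#'   parameters (defaults 1e7 and 1.5).
#' @param cf_shape1,cf_shape2 Beta parameters of the depletion correction
#'   factor (defaults 4 and 2, mean 2/3).
#' @param noise_cv multiplicative intensity noise as a CV (default 0.10).
#' @param dropout_midpoint_frac detection midpoint as a fraction of the
#'   median baseline (default 0.01).
#' @param dropout_slope logistic slope per log10 intensity (default 8, so
#'   the detection transition is confined to about a quarter decade around the
#'   midpoint).
#' @param kd_range log-uniform Kd range in nM (default c(1, 10000)).
#' @param frac_kinase fraction of proteins annotated as protein kinases
#'   (default 0.55); the rest are spread over other direct-binder classes
#'   and indirect interaction partners.
#' @param seed integer seed; output is reproducible given the seed.
#' @return list with class `sim_truth`: `proteins` (data.frame with
#'   baseline, cf, annotation), `compounds` (ids, reference flag),
#'   `targets` (long data.frame compound_id, protein_id, kd), and the noise
#'   and detection parameters.
#' @export
simulate_truth <- function(n_compounds, n_proteins,
                           mean_targets = 5,
                           promiscuity_size = 0.8,
                           n_reference_targets = 76,
                           baseline_median = 1e7,
                           baseline_sdlog = 1.5,
                           cf_shape1 = 4, cf_shape2 = 2,
                           noise_cv = 0.10,
                           dropout_midpoint_frac = 0.01,
                           dropout_slope = 8,
                           kd_range = c(1, 10000),
                           frac_kinase = 0.55,
                           seed = 1L) {
  stopifnot(n_compounds >= 1, n_proteins >= 1)
  set.seed(seed)
  pid <- sprintf("P%04d", seq_len(n_proteins))
  ann_other <- c("lipid kinase", "nucleotide binder", "helicase", "ATPase",
                 "GTPase", "FAD containing", "heme containing",
                 "scaffold adaptor", "interaction partner of kinase",
                 "phosphatase regulatory subunit")
  annotation <- ifelse(stats::runif(n_proteins) < frac_kinase,
                       "protein kinase",
                       sample(ann_other, n_proteins, replace = TRUE))
  proteins <- data.frame(
    protein_id = pid,
    gene_name = sprintf("G%04d", seq_len(n_proteins)),
    baseline = stats::rlnorm(n_proteins, log(baseline_median), baseline_sdlog),
    cf = stats::rbeta(n_proteins, cf_shape1, cf_shape2),
    annotation = annotation,
    stringsAsFactors = FALSE)

  cid <- sprintf("C%03d", seq_len(n_compounds))
  reference <- "REFCMP"
  n_targets <- pmin(n_proteins,
                    1L + stats::rnbinom(n_compounds, size = promiscuity_size,
                                        mu = mean_targets - 1))
  draw_targets <- function(cmp, k) {
    tg <- sample(pid, k)
    data.frame(compound_id = cmp, protein_id = tg,
               kd = exp(stats::runif(k, log(kd_range[1]), log(kd_range[2]))),
               stringsAsFactors = FALSE)
  }
  targets <- vector("list", n_compounds + 1L)
  for (j in seq_len(n_compounds)) {
    targets[[j]] <- draw_targets(cid[j], n_targets[j])
  }
  targets[[n_compounds + 1L]] <-
    draw_targets(reference, min(n_reference_targets, n_proteins))
  structure(list(
    proteins = proteins,
    compounds = data.frame(compound_id = c(cid, reference),
                           is_reference = c(rep(FALSE, n_compounds), TRUE),
                           stringsAsFactors = FALSE),
    targets = do.call(rbind, c(targets, make.row.names = FALSE)),
    noise_cv = noise_cv,
    dropout_midpoint = dropout_midpoint_frac * baseline_median,
    dropout_slope = dropout_slope,
    seed = seed),
    class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", nrow(x$compounds), "compounds x", nrow(x$proteins),
      "proteins,", nrow(x$targets), "true interactions\n")
  invisible(x)
}

#' Expected residual binding under the simulated competition model
#'
#' r(c) = 1 / (1 + c * cf / Kd) for a target (the slope-1 one-site model
#' with bead depletion folded in), r = 1 for a non-target.
#'
#' @param truth a `sim_truth`.
#' @param compound compound id.
#' @param conc concentration in nM.
#' @return numeric vector over all proteins (named by protein id).
#' @export
expected_residual <- function(truth, compound, conc) {
  r <- rep(1, nrow(truth$proteins))
  names(r) <- truth$proteins$protein_id
  tg <- truth$targets[truth$targets$compound_id == compound, ]
  if (nrow(tg) > 0) {
    cf <- truth$proteins$cf[match(tg$protein_id, truth$proteins$protein_id)]
    r[tg$protein_id] <- 1 / (1 + conc * cf / tg$kd)
  }
  r
}

#' Simulate a Kinobeads competition plate
#'
#' Lays out a plate in the assay's design — six randomized DMSO vehicle
#' controls, three replicate wells of the promiscuous reference compound,
#' one depletion pair (two consecutive pulldowns of the vehicle lysate),
#' and either two doses (100 and 1000 nM) or the nine-point full dose
#' ladder (vehicle plus 0.3-1000 nM) per compound — and generates observed
#' intensities from the truth: baseline x expected residual x log-normal
#' noise, with intensity-dependent dropout and Poisson-linked
#' peptide/spectrum counts. With `noise = FALSE` intensities equal their
#' expectations exactly, detection is deterministic and counts are fixed,
#' which closes the loop for exact-recovery tests.
#'
#' @param truth a [simulate_truth()] result.
#' @param compounds compound ids to plate (default: all non-reference
#'   compounds).
#' @param design `"two_dose"` (100 and 1000 nM) or `"full_dose"`
#'   (0.3, 1, 3, 10, 30, 100, 300, 1000 nM).
#' @param noise logical: multiplicative noise + stochastic dropout + count
#'   sampling (TRUE) or the exact expectations (FALSE).
#' @param plate_id plate identifier.
#' @param seed integer seed for this plate's randomness.
#' @return an [experiment_set()].
#' @export
simulate_plate <- function(truth, compounds = NULL,
                           design = c("two_dose", "full_dose"),
                           noise = TRUE, plate_id = "plate1", seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  design <- match.arg(design)
  set.seed(seed)
  if (is.null(compounds)) {
    compounds <- truth$compounds$compound_id[!truth$compounds$is_reference]
  }
  reference <- truth$compounds$compound_id[truth$compounds$is_reference][1]
  doses <- if (design == "two_dose") {
    c(100, 1000)
  } else {
    c(0.3, 1, 3, 10, 30, 100, 300, 1000)
  }
  wells <- list()
  add <- function(role, compound = NA_character_, conc = NA_real_,
                  replicate = NA_integer_) {
    wells[[length(wells) + 1L]] <<- data.frame(
      plate_id = plate_id, well_id = sprintf("W%03d", length(wells) + 1L),
      role = role, compound_id = compound, concentration_nM = conc,
      replicate = replicate, stringsAsFactors = FALSE)
  }
  for (k in 1:6) add("dmso_control")
  for (rep_i in 1:3) {
    for (d in doses) add("reference_replicate", reference, d, rep_i)
  }
  add("depletion_first")
  add("depletion_second")
  for (cmp in compounds) {
    for (d in doses) add("compound", cmp, d)
  }
  layout <- plate_layout(do.call(rbind, c(wells, make.row.names = FALSE)))

  np <- nrow(truth$proteins)
  nw <- nrow(layout)
  baseline <- truth$proteins$baseline
  cf <- truth$proteins$cf
  sigma <- sqrt(log(1 + truth$noise_cv ^ 2))  # log-scale sd giving the CV
  expected <- base::matrix(NA_real_, np, nw,
                           dimnames = list(truth$proteins$protein_id,
                                           layout$well_id))
  for (i in seq_len(nw)) {
    role <- layout$role[i]
    e <- if (role %in% c("compound", "reference_replicate")) {
      baseline * expected_residual(truth, layout$compound_id[i],
                                   layout$concentration_nM[i])
    } else if (role == "depletion_second") {
      baseline * cf   # second consecutive pulldown captures cf of the first
    } else {
      baseline        # dmso_control and depletion_first
    }
    expected[, i] <- e
  }
  if (noise) {
    obs <- expected * exp(base::matrix(stats::rnorm(np * nw, 0, sigma), np, nw))
    p_detect <- stats::plogis(truth$dropout_slope *
                                (log10(pmax(obs, 1e-12)) -
                                   log10(truth$dropout_midpoint)))
    detected <- base::matrix(stats::runif(np * nw) < p_detect, np, nw)
  } else {
    obs <- expected
    detected <- obs > 0
  }
  obs[!detected] <- NA

  # identification depth scales with signal; Poisson-linked when noisy
  lambda <- pmax(log10(pmax(obs, 1)) - log10(truth$dropout_midpoint), 0) + 1
  lambda[!detected] <- 0
  if (noise) {
    peps <- base::matrix(stats::rpois(np * nw, lambda), np, nw)
    msms <- peps + base::matrix(stats::rpois(np * nw, lambda), np, nw)
  } else {
    peps <- round(lambda)
    msms <- 2 * round(lambda)
  }
  peps[detected & peps < 1] <- 1
  msms[detected & msms < 1] <- 1
  peps[!detected] <- 0
  msms[!detected] <- 0
  dimnames(peps) <- dimnames(msms) <- dimnames(obs)

  proteins <- data.frame(protein_id = truth$proteins$protein_id,
                         gene_name = truth$proteins$gene_name,
                         is_reverse = FALSE, is_contaminant = FALSE,
                         annotation = truth$proteins$annotation,
                         stringsAsFactors = FALSE)
  experiment_set(layout, proteins, obs, peps, msms)
}

#' Simulate a TMT phosphoproteomics experiment with known regulation
#'
#' Generates a [phospho_table()] of `n_sites` phosphosites across five
#' treatment channels plus a DMSO control in `n_replicates` biological
#' replicates. Site baselines are log-normal; log2 intensities get
#' independent Gaussian noise per channel; `n_regulated` sites receive the
#' log2 `effect` in the designated treatment channels. An optional
#' per-replicate dropout probability removes a site's whole replicate
#' (TMT missingness is run-level, reporter channels within a run are
#' essentially complete). Sequence windows are random 15-mers with a
#' serine/threonine/tyrosine acceptor, so a subset carries the Ser-Phe
#' motif.
#'
#' @param n_sites,n_regulated site counts (`n_regulated <= n_sites`).
#' @param effect log2 fold change of regulated sites (default -1).
#' @param noise_sd per-channel log2 noise standard deviation (default 0.25).
#' @param n_replicates biological replicates (default 4).
#' @param conditions treatment channel names.
#' @param regulated_conditions channels that receive the effect (default:
#'   all treatments).
#' @param replicate_dropout probability that a site is missing from a whole
#'   replicate (default 0).
#' @param seed integer seed.
#' @return list: `table` (a `phospho_table`), `truth` (data.frame site_id,
#'   regulated).
#' @export
simulate_phospho <- function(n_sites, n_regulated, effect = -1,
                             noise_sd = 0.25, n_replicates = 4,
                             conditions = paste0("T", 1:5),
                             regulated_conditions = NULL,
                             replicate_dropout = 0, seed = 1L) {
  stopifnot(n_regulated <= n_sites)
  set.seed(seed)
  if (is.null(regulated_conditions)) regulated_conditions <- conditions
  channels <- c(conditions, "DMSO")
  sites <- sprintf("S%05d", seq_len(n_sites))
  regulated <- seq_len(n_sites) <= n_regulated
  base_l2 <- stats::rnorm(n_sites, 20, 2)
  x <- array(NA_real_, c(n_sites, length(channels), n_replicates),
             dimnames = list(sites, channels,
                             paste0("rep", seq_len(n_replicates))))
  for (j in seq_len(n_replicates)) {
    for (ch in channels) {
      shift <- ifelse(regulated & ch %in% regulated_conditions, effect, 0)
      x[, ch, j] <- 2 ^ (base_l2 + shift +
                           stats::rnorm(n_sites, 0, noise_sd))
    }
  }
  if (replicate_dropout > 0) {
    drop <- base::matrix(stats::runif(n_sites * n_replicates) <
                           replicate_dropout, n_sites, n_replicates)
    for (j in seq_len(n_replicates)) x[drop[, j], , j] <- NA
  }
  acceptor <- sample(c("S", "T", "Y"), n_sites, replace = TRUE,
                     prob = c(0.7, 0.25, 0.05))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  windows <- vapply(seq_len(n_sites), function(i) {
    w <- sample(aa, 15, replace = TRUE)
    w[8] <- acceptor[i]
    paste(w, collapse = "")
  }, character(1))
  names(windows) <- sites
  list(table = phospho_table(x, windows = windows, control = "DMSO"),
       truth = data.frame(site_id = sites, regulated = regulated,
                          stringsAsFactors = FALSE))
}
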