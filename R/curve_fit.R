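#' Fit a log-logistic dose-response curve
#'
#' Fits residual-binding responses against concentration with bounded
#' least squares (Levenberg-Marquardt via minpack.lm). Two parameterizations
#' are supported:
#'
#' \describe{
#'   \item{`four_param`}{natural-log four-parameter log-logistic
#'     `r(c) = b + (t - b) / (1 + exp(s * (log(c) - log(i))))` with bottom b,
#'     top t, slope s and inflection i (nM). With b = 0, t = 1, s = 1 this is
#'     exactly the one-site competition model `r = 1 / (1 + c / i)`.}
#'   \item{`three_param_log10`}{`r = b + (t - b) / (1 + 10^((log10(i) - log10(c))
#'     * h))` with the hill slope h fixed at 1, the displacement-assay
#'     variant.}
#' }
#'
#' Vehicle measurements enter as concentration 0 and constrain the top
#' asymptote (the curve value at c = 0 is t). Bounds: b in \[0, 1\], t in
#' \[0.5, 1.5\], s > 0, i within \[assay min / 10, assay max * 10\]. Three
#' seeded random restarts are attempted; the best converged fit by residual
#' sum of squares wins. A fit pinned at the upper inflection bound (no
#' response over the assayed range) is flagged `degenerate`.
#'
#' @param concentrations nM, may include 0 for vehicle wells.
#' @param responses relative residual binding, same length.
#' @param model `"four_param"` or `"three_param_log10"`.
#' @param seed integer seed for the restart jitter.
#' @return list with class `curve_fit`: `b`, `t`, `s`, `i`, `rss`,
#'   `converged`, `degenerate`, `model`.
#' @export
fit_log_logistic <- function(concentrations, responses,
                             model = c("four_param", "three_param_log10"),
                             seed = 1L) {
  model <- match.arg(model)
  stopifnot(length(concentrations) == length(responses))
  ok <- !is.na(concentrations) & !is.na(responses)
  conc <- concentrations[ok]
  resp <- responses[ok]
  if (any(conc < 0)) stop("negative concentration")
  pos <- conc[conc > 0]
  n_par <- if (model == "four_param") 4L else 3L
  if (length(unique(pos)) < max(n_par, 5L) && model == "four_param") {
    stop("four-parameter fit needs at least 5 distinct positive concentrations")
  }
  if (length(conc) < n_par) stop("fewer points than parameters")

  lo_i <- min(pos) / 10
  hi_i <- max(pos) * 10
  if (diff(range(resp)) < 1e-10) {
    # flat profile: no competition over the assayed range; report the level
    # with the inflection pinned at the upper bound and flag it
    lev <- mean(resp)
    return(structure(list(b = lev, t = lev, s = 1,
                          i = hi_i, rss = sum((resp - lev) ^ 2),
                          converged = TRUE, degenerate = TRUE, model = model),
                     class = "curve_fit"))
  }
  predict_ll <- function(b, t, s, li, c) {
    out <- rep(t, length(c))             # c = 0 limit is the top asymptote
    p <- c > 0
    if (model == "four_param") {
      out[p] <- b + (t - b) / (1 + exp(s * (log(c[p]) - li)))
    } else {
      out[p] <- b + (t - b) / (1 + 10 ^ ((li / log(10) - log10(c[p])) * 1))
    }
    out
  }
  fail <- structure(list(b = NA_real_, t = NA_real_, s = NA_real_,
                         i = NA_real_, rss = NA_real_, converged = FALSE,
                         degenerate = FALSE, model = model),
                    class = "curve_fit")

  start0 <- list(b = max(0, min(resp)), t = min(1.5, max(0.5, max(resp))),
                 s = 1, li = log(stats::median(pos)))
  lower <- c(b = 0, t = 0.5, s = 1e-3, li = log(lo_i))
  upper <- c(b = 1, t = 1.5, s = 25, li = log(hi_i))
  if (model == "three_param_log10") {
    start0$s <- NULL
    lower <- lower[names(lower) != "s"]
    upper <- upper[names(upper) != "s"]
  }

  set.seed(seed)
  best <- NULL
  for (k in 1:3) {
    start <- start0
    if (k > 1) {  # jittered restarts within bounds
      start$li <- stats::runif(1, log(lo_i), log(hi_i))
      if (model == "four_param") start$s <- stats::runif(1, 0.5, 2)
    }
    fit <- tryCatch({
      if (model == "four_param") {
        minpack.lm::nlsLM(
          resp ~ predict_ll(b, t, s, li, conc),
          start = start, lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12))
      } else {
        minpack.lm::nlsLM(
          resp ~ predict_ll(b, t, 1, li, conc),
          start = start, lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit) ^ 2)
    if (is.null(best) || rss < best$rss - 1e-15) {
      cf <- stats::coef(fit)
      best <- list(b = unname(cf["b"]), t = unname(cf["t"]),
                   s = if (model == "four_param") unname(cf["s"]) else 1,
                   i = exp(unname(cf["li"])), rss = rss)
    }
  }
  if (is.null(best)) return(fail)
  if (best$b > best$t) {                 # canonical orientation: b <= t
    tmp <- best$b; best$b <- best$t; best$t <- tmp
  }
  # no usable response over the assayed range: inflection pinned at a bound
  # or essentially zero dynamic range between the asymptotes
  degenerate <- best$i >= hi_i * (1 - 1e-6) || best$i <= lo_i * (1 + 1e-6) ||
    (best$t - best$b) < 0.05
  structure(list(b = best$b, t = best$t, s = best$s, i = best$i,
                 rss = best$rss, converged = TRUE, degenerate = degenerate,
                 model = model),
            class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  if (!x$converged) {
    cat("curve_fit (", x$model, "): not converged\n", sep = "")
  } else {
    cat(sprintf("curve_fit (%s): b=%.4g t=%.4g s=%.4g i=%.4g nM rss=%.3g%s\n",
                x$model, x$b, x$t, x$s, x$i, x$rss,
                if (x$degenerate) " [degenerate]" else ""))
  }
  invisible(x)
}

#' Evaluate a fitted log-logistic curve
#'
#' @param object a `curve_fit`.
#' @param concentrations nM (0 allowed, giving the top asymptote).
#' @param ... unused.
#' @return predicted relative residual binding.
#' @export
predict.curve_fit <- function(object, concentrations, ...) {
  stopifnot(object$converged)
  out <- rep(object$t, length(concentrations))
  p <- concentrations > 0
  if (object$model == "four_param") {
    out[p] <- object$b + (object$t - object$b) /
      (1 + exp(object$s * (log(concentrations[p]) - log(object$i))))
  } else {
    out[p] <- object$b + (object$t - object$b) /
      (1 + 10 ^ (log10(object$i) - log10(concentrations[p])))
  }
  out
}

#' Full dose-response affinities for a simulated or measured panel
#'
#' Fits every (compound, protein) profile across the full dose ladder with
#' [fit_log_logistic()] and converts the inflection (the assay IC50) to
#' apparent Kd via the depletion correction factor: Kd_app = i * cf.
#' Vehicle wells (the DMSO controls, r = 1 by construction) anchor the top.
#'
#' @param residual_binding a [compute_residual_binding()] result from a
#'   full-dose design.
#' @param cf named correction-factor vector ([compute_correction_factor()]).
#' @param min_reduction profiles whose smallest residual exceeds this value
#'   are skipped as non-binders (default 0.7, as in the two-dose rule).
#' @param seed restart seed.
#' @return data.frame: compound_id, protein_id, b, t, s, i, rss, converged,
#'   degenerate, cf, kd_app, pkd_app.
#' @export
full_dose_affinity <- function(residual_binding, cf, min_reduction = 0.7,
                               seed = 1L) {
  stopifnot(inherits(residual_binding, "residual_binding"))
  prof <- residual_binding$profiles
  fallback <- attr(cf, "global_median")
  if (is.null(fallback)) fallback <- stats::median(cf, na.rm = TRUE)
  pieces <- split(prof[, c("compound_id", "protein_id", "concentration_nM",
                           "r")],
                  paste(prof$compound_id, prof$protein_id, sep = "\r"))
  keys <- do.call(rbind, lapply(pieces, function(p) p[1, 1:2]))
  rows <- vector("list", length(pieces))
  for (j in seq_along(pieces)) {
    conc <- pieces[[j]]$concentration_nM
    resp <- pieces[[j]]$r
    # vehicle anchor: the DMSO wells define r = 1 at c = 0
    conc <- c(conc, 0)
    resp <- c(resp, 1)
    if (min(resp) > min_reduction) next
    ft <- fit_log_logistic(conc, resp, model = "four_param", seed = seed)
    cfp <- unname(cf[keys$protein_id[j]])
    if (is.na(cfp)) cfp <- fallback
    kd <- if (ft$converged && !ft$degenerate) ft$i * cfp else NA_real_
    rows[[j]] <- data.frame(
      compound_id = keys$compound_id[j], protein_id = keys$protein_id[j],
      b = ft$b, t = ft$t, s = ft$s, i = ft$i, rss = ft$rss,
      converged = ft$converged, degenerate = ft$degenerate,
      cf = cfp, kd_app = kd,
      pkd_app = ifelse(is.finite(kd) & kd > 0, -log10(kd * 1e-9), NA_real_),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows[!vapply(rows, is.null, TRUE)],
                   make.row.names = FALSE))
}
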