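# helper: residual_binding object built directly from r values at two doses
rb_from_r <- function(r100, r1000, protein = "P1", compound = "drugA") {
  prof <- data.frame(
    plate_id = "p1", well_id = c("w1", "w2"), compound_id = compound,
    replicate = NA_integer_, concentration_nM = c(100, 1000),
    protein_id = protein, r = c(r100, r1000), imputed = FALSE,
    stringsAsFactors = FALSE)
  st <- data.frame(plate_id = "p1", protein_id = protein, dmso_median = 1e6,
                   dmso_std = 0.05, n_dmso_quantified = 6,
                   max_unique_peptides = 5, max_msms = 10,
                   stringsAsFactors = FALSE)
  structure(list(profiles = prof, stats = st), class = "residual_binding")
}

test_that("two-dose IC50 inverts the one-site model at the chosen dose", {
  # r = 0.5 at 100 nM: the symmetric point, IC50 = [I]
  est <- estimate_ic50_two_dose(rb_from_r(0.5, 0.15))
  expect_equal(est$chosen_concentration, 100)
  expect_equal(est$ic50, 100)

  # r(100)=0.8, r(1000)=0.4: top dose is closer to half-maximal
  est <- estimate_ic50_two_dose(rb_from_r(0.8, 0.4))
  expect_equal(est$chosen_concentration, 1000)
  expect_equal(est$ic50, 1000 * 0.4 / 0.6)
  expect_equal(est$flag, "ok")

  # tie on |r - 0.5| goes to the lower dose
  est <- estimate_ic50_two_dose(rb_from_r(0.6, 0.4))
  expect_equal(est$chosen_concentration, 100)
})

test_that("non-binders and beyond-assay estimates are flagged", {
  est <- estimate_ic50_two_dose(rb_from_r(0.99, 0.99))
  expect_equal(est$flag, "non_binder")
  expect_true(is.infinite(est$ic50))

  est <- estimate_ic50_two_dose(rb_from_r(0.9, 0.6))
  expect_equal(est$flag, "above_assay_max")
  expect_true(is.finite(est$ic50))

  expect_error(
    estimate_ic50_two_dose(rb_from_r(0.5, 0.2), doses = c(10, 1000)),
    "doses")
})

test_that("IC50 is monotone in the chosen-dose residual and never negative", {
  # keep |r_high - 0.5| < |r_low - 0.5| so the chosen dose stays the top dose
  rs <- seq(0.15, 0.45, by = 0.05)
  ic <- vapply(rs, function(r) {
    estimate_ic50_two_dose(rb_from_r(0.9, r))$ic50
  }, numeric(1))
  expect_true(all(diff(ic) > 0))
  expect_true(all(ic > 0))
  # clamping keeps extreme residuals finite and positive
  est <- estimate_ic50_two_dose(rb_from_r(0.4, 0))
  expect_gt(est$ic50, 0)
})

test_that("correction factors are capped ratios with sensible edge cases", {
  cf <- compute_correction_factor(first = c(a = 100, b = 100, c = 100),
                                  second = c(a = 100, b = 0, c = 30))
  expect_equal(as.numeric(cf), c(1, 0, 0.3))
  # second pulldown exceeding the first caps at one
  cf <- compute_correction_factor(first = c(a = 50), second = c(a = 80))
  expect_equal(as.numeric(cf), 1)
  expect_warning(
    cf <- compute_correction_factor(first = c(a = 0), second = c(a = 10)),
    "zero")
  expect_equal(as.numeric(cf), 1)
})

test_that("depletion correction multiplies and converts units", {
  est <- estimate_ic50_two_dose(rb_from_r(0.8, 0.4))
  out <- apply_depletion_correction(est, c(P1 = 0.5))
  expect_equal(out$kd_app, out$ic50 * 0.5)
  expect_equal(out$kd_app, 1000 * 0.4 / 0.6 * 0.5, tolerance = 1e-12)
  # Kd_app of 100 nM is pKd 7
  out2 <- apply_depletion_correction(data.frame(protein_id = "P1", ic50 = 100),
                                     c(P1 = 1))
  expect_equal(out2$kd_app, 100)
  expect_equal(out2$pkd_app, 7)
  # cf = 1 leaves the IC50 untouched; sentinels propagate
  out3 <- apply_depletion_correction(
    data.frame(protein_id = c("P1", "P2"), ic50 = c(50, Inf)),
    c(P1 = 1, P2 = 0.4))
  expect_equal(out3$kd_app, c(50, Inf))
  expect_true(is.na(out3$pkd_app[2]))
  expect_true(all(out3$kd_app <= out3$ic50))
})

test_that("missing proteins fall back to the global median cf", {
  cf <- compute_correction_factor(first = c(a = 100, b = 100, c = 100),
                                  second = c(a = 20, b = 60, c = 100))
  est <- data.frame(protein_id = "unseen", ic50 = 100)
  out <- apply_depletion_correction(est, cf)
  expect_equal(out$cf, 0.6)  # median of 0.2, 0.6, 1.0
})

test_that("noiseless two-dose recovery is exact for in-range residuals", {
  tr <- simulate_truth(10, 150, seed = 3)
  es <- simulate_plate(tr, design = "two_dose", noise = FALSE, seed = 4)
  out <- run_two_dose_pipeline(es, seed = 5)
  m <- merge(out$estimates, tr$targets, by = c("compound_id", "protein_id"))
  cf_true <- setNames(tr$proteins$cf, tr$proteins$protein_id)
  r_chosen <- 1 / (1 + m$chosen_concentration * cf_true[m$protein_id] / m$kd)
  in_range <- r_chosen >= 1e-3 & r_chosen <= 1 - 1e-3 & m$flag == "ok"
  expect_gt(sum(in_range), 20)
  expect_lt(max(abs(m$kd_app[in_range] - m$kd[in_range]) / m$kd[in_range]),
            1e-9)
})

test_that("the 4PL fit recovers noiseless parameters and the inflection identity", {
  doses <- c(0.3, 1, 3, 10, 30, 100, 300, 1000)
  truth <- list(b = 0.1, t = 1.0, s = 1.2, i = 50)
  r <- truth$b + (truth$t - truth$b) /
    (1 + exp(truth$s * (log(doses) - log(truth$i))))
  ft <- fit_log_logistic(c(doses, 0), c(r, truth$t), model = "four_param")
  expect_true(ft$converged)
  expect_equal(ft$b, truth$b, tolerance = 1e-6)
  expect_equal(ft$t, truth$t, tolerance = 1e-6)
  expect_equal(ft$s, truth$s, tolerance = 1e-5)
  expect_equal(ft$i, truth$i, tolerance = 1e-5)
  # slope 1, inflection 100: the curve passes through (100, midpoint)
  r2 <- 1 / (1 + doses / 100)
  ft2 <- fit_log_logistic(doses, r2, model = "four_param")
  expect_equal(predict(ft2, 100), (ft2$b + ft2$t) / 2, tolerance = 1e-6)
  expect_equal(predict(ft2, 100), 0.5, tolerance = 1e-6)
})

test_that("flat profiles converge to a degenerate fit and contracts hold", {
  doses <- c(0.3, 1, 3, 10, 30, 100, 300, 1000)
  ft <- fit_log_logistic(doses, rep(1, 8), model = "four_param")
  expect_true(ft$converged)
  expect_true(ft$degenerate)
  expect_error(fit_log_logistic(c(1, 10, 100), c(1, 0.5, 0.2),
                                model = "four_param"),
               "distinct positive")
})

test_that("the three-parameter displacement variant fits its own curve", {
  doses <- 10 ^ seq(0, 3, length.out = 8)
  r <- 0.05 + (1 - 0.05) / (1 + 10 ^ (log10(40) - log10(doses)))
  ft <- fit_log_logistic(doses, r, model = "three_param_log10")
  expect_true(ft$converged)
  expect_equal(ft$i, 40, tolerance = 1e-4)
  expect_equal(ft$b, 0.05, tolerance = 1e-4)
})
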