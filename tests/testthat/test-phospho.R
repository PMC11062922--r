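pt_from_array <- function(x, windows = NULL) {
  phospho_table(x, windows = windows, control = "DMSO")
}

test_that("total-sum normalization equalizes channel sums to the control", {
  x <- array(NA_real_, c(2, 2, 1),
             dimnames = list(c("s1", "s2"), c("T1", "DMSO"), "rep1"))
  x[, "T1", 1] <- c(150, 50)    # sum 200
  x[, "DMSO", 1] <- c(60, 40)   # sum 100
  out <- total_sum_normalize(pt_from_array(x))
  expect_equal(unname(out$intensity[, "T1", 1]), c(75, 25))  # scaled by 0.5
  expect_equal(sum(out$intensity[, "T1", 1]), sum(out$intensity[, "DMSO", 1]))
  # already equal sums: identity
  again <- total_sum_normalize(out)
  expect_equal(again$intensity, out$intensity)
})

test_that("channel sums after normalization match the control to 1e-9", {
  set.seed(141)
  for (i in 1:5) {
    x <- array(rlnorm(50 * 6 * 4, 10, 1), c(50, 6, 4),
               dimnames = list(sprintf("s%02d", 1:50),
                               c(paste0("T", 1:5), "DMSO"),
                               paste0("rep", 1:4)))
    x[runif(length(x)) < 0.05] <- NA
    out <- total_sum_normalize(pt_from_array(x))
    for (j in 1:4) {
      sums <- colSums(out$intensity[, , j], na.rm = TRUE)
      expect_lt(max(abs(sums / sums["DMSO"] - 1)), 1e-9)
    }
  }
})

test_that("row-wise normalization scales each site's mean of replicate means to 1", {
  x <- array(NA_real_, c(1, 2, 2),
             dimnames = list("s1", c("T1", "DMSO"), c("rep1", "rep2")))
  x[1, , 1] <- c(2, 2)   # replicate mean 2
  x[1, , 2] <- c(4, 4)   # replicate mean 4
  out <- row_wise_normalize(pt_from_array(x))
  expect_equal(unname(out$intensity[1, , 1]), c(2, 2) / 3)
  expect_equal(unname(out$intensity[1, , 2]), c(4, 4) / 3)
  rep_means <- apply(out$intensity, c(1, 3), mean, na.rm = TRUE)
  expect_equal(unname(rowMeans(rep_means)), 1)
})

test_that("row-wise normalization handles single-replicate sites and is idempotent", {
  set.seed(151)
  x <- array(rlnorm(30 * 6 * 4, 8, 1), c(30, 6, 4),
             dimnames = list(sprintf("s%02d", 1:30),
                             c(paste0("T", 1:5), "DMSO"), paste0("rep", 1:4)))
  x[1, , 2:4] <- NA      # site detected in one replicate only
  x[2, , ] <- NA         # site absent everywhere: dropped
  expect_message(out <- row_wise_normalize(pt_from_array(x)), "dropping 1")
  expect_equal(dim(out$intensity)[1], 29)
  rep_means <- apply(out$intensity, c(1, 3), mean, na.rm = TRUE)
  expect_equal(unname(rowMeans(rep_means, na.rm = TRUE)),
               rep(1, 29), tolerance = 1e-12)
  out2 <- row_wise_normalize(out)
  expect_equal(out2$intensity, out$intensity, tolerance = 1e-12)
})

test_that("identical condition and control values give a null statistic", {
  x <- array(NA_real_, c(60, 2, 4),
             dimnames = list(sprintf("s%02d", 1:60), c("T1", "DMSO"),
                             paste0("rep", 1:4)))
  set.seed(161)
  base <- matrix(rlnorm(60 * 4, 10, 0.3), 60, 4)
  x[, "T1", ] <- base
  x[, "DMSO", ] <- base
  res <- test_regulation(pt_from_array(x), "T1", null = "t")
  expect_true(all(res$stat == 0))
  expect_false(any(res$significant))
})

test_that("q values are nondecreasing in p rank and s0 is validated", {
  sim <- simulate_phospho(300, 20, seed = 171)
  tab <- row_wise_normalize(total_sum_normalize(sim$table))
  res <- test_regulation(tab, "T1", null = "t")
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  expect_error(test_regulation(tab, "T1", s0 = -0.5), "nonnegative")
})

test_that("the replicate filter excludes sites under 3 of 4 replicates", {
  sim <- simulate_phospho(200, 10, replicate_dropout = 0.25, seed = 181)
  tab <- sim$table
  res <- test_regulation(tab, "T1")
  expect_true(all(res$n_replicates_detected >= 3))
  x <- tab$intensity
  complete <- is.finite(x[, "T1", ]) & is.finite(x[, "DMSO", ])
  expect_setequal(res$site_id, rownames(x)[rowSums(complete) >= 3])
})

test_that("regulated sites are recovered with controlled false discoveries", {
  sim <- simulate_phospho(1000 + 50, 50, effect = -1, noise_sd = 0.25,
                          n_replicates = 4, seed = 191)
  tab <- row_wise_normalize(total_sum_normalize(sim$table))
  res <- test_regulation(tab, "T3", s0 = 0.1, fdr = 0.01)
  truth <- sim$truth$regulated[match(res$site_id, sim$truth$site_id)]
  called <- res$significant
  expect_gt(sum(called & truth) / 50, 0.7)
  fdp <- if (any(called)) mean(!truth[called]) else 0
  expect_lt(fdp, 0.1)
  # direction of the injected effect is recovered
  expect_true(all(res$log2fc[called & truth] < 0))
})

test_that("under the global null few sites reach 1 percent FDR", {
  for (seed in c(201, 202)) {
    sim <- simulate_phospho(400, 0, seed = seed)
    tab <- row_wise_normalize(total_sum_normalize(sim$table))
    res <- test_regulation(tab, "T2", s0 = 0.1, fdr = 0.01)
    expect_lt(mean(res$significant), 0.03)
  }
})

test_that("condition intersection keeps consistently down-regulated sites", {
  expect_equal(intersect_conditions(list(c("A", "B", "C"), c("A", "B"), "A")),
               "A")
  mk <- function(sites, fc, sig = TRUE) {
    data.frame(site_id = sites, log2fc = fc, significant = sig,
               stringsAsFactors = FALSE)
  }
  res <- list(mk(c("s1", "s2"), c(-1, -2)),
              mk(c("s1", "s2"), c(-1, 2)))   # s2 flips direction
  expect_equal(intersect_conditions(res), "s1")
  expect_error(intersect_conditions(list(c("A"))), "at least 2")
  # monotone in the number of conditions
  sets <- list(c("A", "B", "C", "D"), c("A", "B", "C"), c("A", "B"))
  sizes <- vapply(2:3, function(k) {
    length(intersect_conditions(sets[1:k]))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("the Ser-Phe motif check is literal about residue and position", {
  expect_true(motif_check("AAAAAAASFAAAAAA"))
  expect_false(motif_check("AAAAAAASAAAAAAA"))
  expect_false(motif_check("AAAAAAATFAAAAAA"))  # Thr acceptor does not count
  expect_error(motif_check("SF"), "15 residues")
  expect_equal(motif_check(c("AAAAAAASFAAAAAA", "GGGGGGGSFGGGGGG",
                             "GGGGGGGYFGGGGGG")),
               c(TRUE, TRUE, FALSE))
})

test_that("the s0 percentile estimator returns a value on the se scale", {
  sim <- simulate_phospho(500, 25, seed = 211)
  tab <- row_wise_normalize(total_sum_normalize(sim$table))
  s0 <- estimate_s0(tab, "T1")
  expect_true(is.finite(s0) && s0 >= 0)
  expect_lt(s0, 1)
})
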