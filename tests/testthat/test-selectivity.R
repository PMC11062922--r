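test_that("engagement is the slope-1 binding isotherm", {
  expect_equal(engagement(50, 50), 0.5)
  expect_equal(engagement(10, 100), 10 / 110)
  e <- engagement(10 ^ seq(0, 6, by = 0.5), 100)
  expect_true(all(diff(e) > 0))
  expect_lt(1 - engagement(1e9, 100), 1e-6)
  expect_error(engagement(-1, 10), "positive")
  expect_error(engagement(10, 0), "positive")
})

test_that("catds equals term-by-term evaluation on the worked example", {
  kds <- c(A = 10, B = 100)
  sc <- catds(kds, "A")
  expect_equal(sc$cstar, 10)
  expect_equal(sc$numerator, 0.5)
  expect_equal(sc$denominator, 0.5 + 10 / 110)
  expect_equal(sc$catds, 0.5 / (0.5 + 10 / 110))
  expect_equal(round(sc$catds, 3), 0.846)

  # single target: perfect selectivity whatever the Kd
  expect_equal(catds(c(X = 321), "X")$catds, 1)
  expect_error(catds(c(A = 10), "missing"), "subset")
  expect_error(catds(numeric(0), "A"), "empty")
})

test_that("a paralog group covering the whole target set scores exactly 1", {
  kds <- c(CSNK2A1 = 78, CSNK2A2 = 310)
  groups <- list(CK2 = c("CSNK2A1", "CSNK2A2"))
  sc <- catds(kds, "CK2", groups = groups)
  expect_equal(sc$catds, 1)
  expect_equal(sc$cstar, 78)   # most potent member sets c*
  # same group semantics with an off-target present
  kds2 <- c(kds, OFF = 500)
  sc2 <- catds(kds2, "CK2", groups = groups)
  expect_lt(sc2$catds, 1)
})

test_that("catds_most_potent has an exactly half-maximal numerator", {
  sc <- catds_most_potent(c(A = 10, B = 100))
  expect_identical(sc$numerator, 0.5)
  expect_equal(sc$catds, 0.5 / (0.5 + 10 / 110))
  # two equal-Kd targets split engagement evenly: exactly 0.5
  sc2 <- catds_most_potent(c(B = 40, A = 40))
  expect_identical(sc2$catds, 0.5)
  expect_equal(sc2$members, "A")  # lexicographic tie-break
  expect_equal(catds_most_potent(c(only = 5))$catds, 1)
})

test_that("catds matches an independent oracle on random Kd vectors", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    kds <- setNames(exp(runif(n, 0, 9)), sprintf("T%02d", seq_len(n)))
    ref <- sample(names(kds), 1)
    cstar <- unname(kds[ref])
    sc <- catds(kds, ref, cstar = cstar)
    oracle <- sum(cstar / (cstar + kds[ref])) /
      sum(cstar / (cstar + kds))
    expect_equal(sc$catds, oracle, tolerance = 1e-12)
    mp <- catds_most_potent(kds)
    best <- names(kds)[order(kds, names(kds))[1]]
    o2 <- 0.5 / sum(kds[best] / (kds[best] + kds))
    expect_equal(mp$catds, o2, tolerance = 1e-12)
  }
})

test_that("catds is scale invariant and decreases with added off-targets", {
  kds <- c(A = 20, B = 300, C = 4000)
  sc <- catds(kds, "A")
  sc_scaled <- catds(kds * 7, "A", cstar = sc$cstar * 7)
  expect_equal(sc$catds, sc_scaled$catds, tolerance = 1e-12)
  sc_more <- catds(c(kds, D = 1500), "A")
  expect_lt(sc_more$catds, sc$catds)
})

make_dtm <- function(df) {
  df$pkd_app <- -log10(df$kd_app * 1e-9)
  if (is.null(df$flag)) df$flag <- rep("ok", nrow(df))
  df$is_target <- rep(TRUE, nrow(df))
  class(df) <- c("drug_target_matrix", "data.frame")
  df
}

test_that("probe nomination applies the strict affinity and selectivity criteria", {
  dtm <- make_dtm(data.frame(
    compound_id = c("single", "weak", "weak", "boundary", "boundary2"),
    protein_id = c("K1", "K2", "K3", "K4", "K5"),
    kd_app = c(80, 1200, 5000, 1000, 400),
    stringsAsFactors = FALSE))
  out <- nominate_probes(dtm)
  expect_true(out$passes[out$compound_id == "single"])
  # best Kd 1200 nM fails the affinity criterion despite high selectivity
  expect_false(out$passes[out$compound_id == "weak"])
  # Kd exactly 1000 nM is excluded by the strict inequality
  expect_false(out$passes[out$compound_id == "boundary"])
  expect_true(out$passes[out$compound_id == "boundary2"])
  # equal-Kd pair scores exactly 0.5 and is excluded by the strict inequality
  dtm2 <- make_dtm(data.frame(compound_id = "dual", protein_id = c("A", "B"),
                              kd_app = c(100, 100)))
  expect_false(nominate_probes(dtm2)$passes)
})

test_that("probe nomination equals a brute-force filter on random matrices", {
  set.seed(111)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    dtm <- make_dtm(data.frame(
      compound_id = sample(sprintf("c%02d", 1:8), n, replace = TRUE),
      protein_id = sample(sprintf("K%02d", 1:15), n, replace = TRUE),
      kd_app = exp(runif(n, 0, 9)), stringsAsFactors = FALSE))
    dtm <- dtm[!duplicated(dtm[, c("compound_id", "protein_id")]), ]
    out <- nominate_probes(dtm)
    brute <- vapply(out$compound_id, function(cmp) {
      kds <- dtm$kd_app[dtm$compound_id == cmp]
      names(kds) <- dtm$protein_id[dtm$compound_id == cmp]
      kmin <- min(kds)
      cs <- 0.5 / sum(kmin / (kmin + kds))
      kmin < 1000 && cs > 0.5
    }, logical(1))
    expect_equal(out$passes, unname(brute))
  }
})

test_that("the landscape summary matches hand enumeration and is permutation invariant", {
  dtm <- make_dtm(data.frame(
    compound_id = c("c1", "c1", "c2", "c3"),
    protein_id = c("K1", "K2", "K1", "K2"),
    kd_app = c(50, 2000, 800, 900), stringsAsFactors = FALSE))
  s <- summarize_landscape(dtm, all_compounds = c("c1", "c2", "c3", "c4"))
  expect_equal(s$n_kinases_targeted, 2)
  expect_equal(s$n_kinases_submicromolar, 2)  # K1 via c1/c2, K2 via c3
  expect_equal(s$n_pairs_submicromolar, 3)
  expect_equal(s$n_compounds_no_target, 1)    # c4
  expect_equal(s$n_compounds_no_submicromolar, 1)
  expect_true(s$n_pairs_submicromolar >= s$n_kinases_submicromolar)

  set.seed(121)
  perm <- dtm[sample(nrow(dtm)), ]
  s2 <- summarize_landscape(perm, all_compounds = c("c1", "c2", "c3", "c4"))
  expect_equal(s2$n_kinases_targeted, s$n_kinases_targeted)
  expect_equal(s2$n_pairs_submicromolar, s$n_pairs_submicromolar)

  empty <- make_dtm(data.frame(compound_id = character(),
                               protein_id = character(),
                               kd_app = numeric()))
  s0 <- summarize_landscape(empty)
  expect_equal(s0$n_kinases_targeted, 0)
  expect_equal(s0$n_pairs_submicromolar, 0)
})
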