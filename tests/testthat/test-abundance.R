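test_that("relative abundance reproduces the hand-computed two-codon case", {
  # class means: AGG (4, 2), CAA (2, 3) -> diffs (2, -1), alpha_max = 2,
  # beta_rel = (1.0, -0.5)
  me <- matrix(c(4, 4, 2, 2), nrow = 2,
               dimnames = list(NULL, c("AGG", "CAA")))
  mn <- matrix(c(2, 2, 3, 3), nrow = 2,
               dimnames = list(NULL, c("AGG", "CAA")))
  pd <- paired_from_matrices(me, mn)
  ab <- relative_abundance(pd, c("AGG", "CAA"))
  expect_equal(ab$diff, c(2, -1))
  expect_equal(attr(ab, "alpha_max"), 2)
  expect_equal(ab$beta_rel, c(1.0, -0.5))
  expect_identical(positive_contributors(ab), "AGG")

  # literal signed-max convention: alpha_max still 2 here, but with the
  # larger difference negative the normalisation changes
  ab2 <- relative_abundance(pd, c("AGG", "CAA"), alpha_max = "signed")
  expect_equal(ab2$beta_rel, c(1.0, -0.5))
  mn_flip <- me; me_flip <- mn
  ab3 <- relative_abundance(paired_from_matrices(me_flip, mn_flip),
                            c("AGG", "CAA"), alpha_max = "signed")
  expect_equal(attr(ab3, "alpha_max"), 1)   # max{-2, 1} = 1
  expect_equal(ab3$beta_rel, c(-2, 1))      # unbounded below
})

test_that("identical matrices give all-zero abundance with a warning", {
  me <- matrix(runif(8, 1, 5), nrow = 4,
               dimnames = list(NULL, c("AAA", "AAC")))
  pd <- paired_from_matrices(me, me)
  expect_warning(ab <- relative_abundance(pd, c("AAA", "AAC")), "zero")
  expect_equal(ab$diff, c(0, 0))
  expect_equal(ab$beta_rel, c(0, 0))
  expect_error(relative_abundance(pd, character(0)), "empty")
})

test_that("a single significant codon self-normalises to |beta_rel| = 1", {
  me <- matrix(c(4, 4), ncol = 1, dimnames = list(NULL, "AGG"))
  mn <- matrix(c(2, 2), ncol = 1, dimnames = list(NULL, "AGG"))
  ab <- relative_abundance(paired_from_matrices(me, mn), "AGG")
  expect_equal(abs(ab$beta_rel), 1)
})

test_that("beta_rel sign tracks the mean difference and stays within [-1, 1]", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(2:8, 1)
    k <- sample(2:10, 1)
    cods <- sample(codon_alphabet(), k)
    me <- matrix(runif(n * k, 0, 10), nrow = n, dimnames = list(NULL, cods))
    mn <- matrix(runif(n * k, 0, 10), nrow = n, dimnames = list(NULL, cods))
    ab <- relative_abundance(paired_from_matrices(me, mn), cods)
    expect_true(all(abs(ab$beta_rel) <= 1 + 1e-12))
    expect_true(all(sign(ab$beta_rel) == sign(ab$diff)))
  }
})

test_that("interval scaling maps ratio weights onto [1, 9] as derived by hand", {
  rk <- rank_codons(c(CAA = 0.5, ACC = 1.0, AGG = 1.5))
  expect_equal(rk$W, c(1, 5, 9))
  expect_identical(rk$rank, c(1L, 5L, 9L))

  rk2 <- rank_codons(c(AAA = 0.8, TTT = 1.3))
  expect_identical(rk2$rank, c(1L, 9L))
})

test_that("rank endpoints and monotonicity hold for random ratio weights", {
  set.seed(5)
  for (i in 1:100) {
    k <- sample(2:20, 1)
    xi <- stats::setNames(runif(k, 0.1, 4), sample(codon_alphabet(), k))
    rk <- rank_codons(xi)
    expect_true(all(rk$W >= 1 - 1e-12 & rk$W <= 9 + 1e-12))
    expect_identical(rk$rank[which.max(rk$xi)], 9L)
    expect_identical(rk$rank[which.min(rk$xi)], 1L)
    expect_true(all(diff(rk$rank[order(rk$xi)]) >= 0))
  }
})

test_that("rank table from an abundance result uses mean ratios", {
  me <- matrix(c(2, 2, 1, 1, 3, 3), nrow = 2,
               dimnames = list(NULL, c("AGG", "CAA", "GAC")))
  mn <- matrix(c(4, 4, 1, 1, 2, 2), nrow = 2,
               dimnames = list(NULL, c("AGG", "CAA", "GAC")))
  pd <- paired_from_matrices(me, mn)
  ab <- relative_abundance(pd, c("AGG", "CAA", "GAC"))
  rk <- rank_codons(ab)
  expect_equal(rk$xi, c(0.5, 1.0, 1.5))
  expect_identical(rk$rank, c(1L, 5L, 9L))
})

test_that("degenerate ratio weights fall back with warnings", {
  # all ratio weights equal -> every codon rank 5
  expect_warning(rk <- rank_codons(c(AAA = 1, CCC = 1, GGG = 1)), "rank 5")
  expect_identical(rk$rank, c(5L, 5L, 5L))

  # zero counterpart mean -> pseudocount fallback, flagged
  me <- matrix(c(2, 2, 1, 1), nrow = 2, dimnames = list(NULL, c("AGG", "CAA")))
  mn <- matrix(c(0, 0, 1, 1), nrow = 2, dimnames = list(NULL, c("AGG", "CAA")))
  ab <- relative_abundance(paired_from_matrices(me, mn), c("AGG", "CAA"))
  expect_warning(rk <- rank_codons(ab), "pseudocount")
  expect_true(rk$pseudocount[rk$codon == "AGG"])
  expect_false(rk$pseudocount[rk$codon == "CAA"])
})

test_that("extreme codons break exact ties lexicographically", {
  rk <- rank_codons(c(AGG = 1.5, AGA = 1.5, CAA = 0.5))
  ex <- extreme_codons(rk)
  expect_identical(ex$highest, "AGA")
  expect_identical(ex$lowest, "CAA")

  expect_warning(one <- rank_codons(c(GGG = 1.2)))
  expect_identical(extreme_codons(one)$highest, extreme_codons(one)$lowest)
})

test_that("data-point series normalise by the global maximum", {
  me <- matrix(c(2, 4, 8), ncol = 1, dimnames = list(NULL, "AGG"))
  mn <- matrix(c(1, 2, 4), ncol = 1, dimnames = list(NULL, "AGG"))
  dp <- datapoint_series(paired_from_matrices(me, mn), "AGG")
  expect_equal(dp$value_e, c(0.25, 0.5, 1.0))
  expect_equal(dp$value_ne, c(0.125, 0.25, 0.5))
  expect_true(max(dp$value_e, dp$value_ne) == 1)

  # all equal and positive -> all 1
  m1 <- matrix(rep(3, 3), ncol = 1, dimnames = list(NULL, "CAA"))
  dp1 <- datapoint_series(paired_from_matrices(m1, m1), "CAA")
  expect_true(all(dp1$value_e == 1) && all(dp1$value_ne == 1))

  # absent codon -> zero series with warning
  expect_warning(
    dp0 <- datapoint_series(paired_from_matrices(m1, m1), "GGG"),
    "absent"
  )
  expect_true(all(dp0$value_e == 0))
})
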