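test_that("profile biasing renormalises within the family", {
  p <- make_profiles(class_codon_profile(), list(bias_spec("CAG", 0.3)))
  expect_equal(unname(p[["Q"]][c("CAA", "CAG")]), c(0.2, 0.8))

  # identity under zero bias
  p0 <- make_profiles(class_codon_profile(), list(bias_spec("CAG", 0)))
  expect_equal(p0[["Q"]], class_codon_profile()[["Q"]])

  # six-codon family: remainder spread proportionally
  p6 <- make_profiles(class_codon_profile(), list(bias_spec("AGG", 0.3)))
  fam <- p6[["R"]]
  expect_equal(unname(fam["AGG"]), 1 / 6 + 0.3)
  expect_equal(sum(fam), 1)
  others <- fam[setdiff(names(fam), "AGG")]
  expect_true(all(abs(others - others[1]) < 1e-12))
})

test_that("biases that break the probability simplex are errors, not clips", {
  expect_error(make_profiles(class_codon_profile(),
                             list(bias_spec("CAG", 0.6))), "outside")
  expect_error(make_profiles(class_codon_profile(),
                             list(bias_spec("CAG", -0.6))), "outside")
  expect_error(make_profiles(class_codon_profile(),
                             list(bias_spec("ATG", 0.1))), "outside")
  expect_silent(make_profiles(class_codon_profile(),
                              list(bias_spec("ATG", 0))))
})

test_that("generated pairs are homologous: identical protein, divergent codons", {
  cfg <- thermophile_config(n_pairs = 15, gene_length = 60, seed = 21)
  ds <- generate_dataset(cfg)
  for (i in seq_len(15)) {
    e <- ds$records[[ds$manifest$ext_id[i]]]
    c_ <- ds$records[[ds$manifest$ctl_id[i]]]
    expect_identical(translate_codons(e$codons), translate_codons(c_$codons))
  }
  expect_identical(length(ds$records), 30L)
  expect_identical(nrow(ds$manifest), 15L)
})

test_that("a degenerate profile makes encoding deterministic", {
  fams <- codon_families()
  det <- lapply(fams, function(cs) {
    stats::setNames(c(1, rep(0, length(cs) - 1)), cs)
  })
  prof <- class_codon_profile(overrides = det)
  pair <- generate_pair(c("M", "Q", "R"), prof, prof)
  expect_identical(pair$codons_e, pair$codons_ne)
  expect_identical(translate_codons(pair$codons_e), "MQR")
})

test_that("the same seed yields byte-identical datasets", {
  cfg <- thermophile_config(n_pairs = 10, gene_length = 50, seed = 33)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- generate_dataset(thermophile_config(n_pairs = 10, gene_length = 50,
                                            seed = 34))
  expect_false(identical(d1$records, d3$records))
})

test_that("empirical codon percentages converge to the closed-form expectation", {
  # long genes: observed mean % of the biased codon within 3 standard
  # errors of family probability x amino-acid frequency x 100
  cfg <- gac_config(n_pairs = 30, gene_length = 10000, seed = 5)
  ds <- generate_dataset(cfg)
  pd <- as_paired_dataset(ds)
  gt <- ds$ground_truth
  for (cod in c("GAC", "GAT", "AGG", "CAA")) {
    exp_e <- gt$expected_pct_e[cod]
    obs <- pd$matrix_e[, cod]
    se <- stats::sd(obs) / sqrt(length(obs))
    expect_lt(abs(mean(obs) - exp_e), 3 * se + 1e-9)
  }
  expect_equal(gt$expected_displacement[["GAC"]],
               100 * 0.3 * (1 / 20) * 10000 / 10001)
})

test_that("invalid configurations enumerate their problems", {
  err <- expect_error(synth_config(n_pairs = 0, gene_length = 5, seed = NA))
  msg <- conditionMessage(err)
  expect_match(msg, "n_pairs")
  expect_match(msg, "gene_length")
  expect_match(msg, "seed")
})

test_that("written datasets are consumable by the I/O layer unchanged", {
  dir <- withr::local_tempdir()
  cfg <- thermophile_config(n_pairs = 6, gene_length = 40, seed = 8)
  ds <- generate_dataset(cfg)
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))

  recs <- c(read_cds_fasta(paths["fasta_e"]),
            read_cds_fasta(paths["fasta_ne"]))
  man <- load_manifest(paths["manifest"], records = recs)
  pd_files <- build_paired_dataset(man, recs)
  pd_mem <- as_paired_dataset(ds)
  expect_equal(pd_files$matrix_e, pd_mem$matrix_e)
  expect_equal(pd_files$matrix_ne, pd_mem$matrix_ne)
})

test_that("zero-bias pairs produce exchangeable codon distributions", {
  # null simulation: flag fraction over codons stays near alpha (the
  # paired design and tied counts make the unpaired KS conservative, so
  # test only the upper side here)
  flagged <- sapply(1:10, function(s) {
    cfg <- synth_config(n_pairs = 60, gene_length = 300, seed = 400 + s)
    pd <- as_paired_dataset(generate_dataset(cfg))
    attr(filter_significant(pd, alpha = 0.05), "n_significant")
  })
  expect_lt(sum(flagged) / (10 * 64), 0.08)
})
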