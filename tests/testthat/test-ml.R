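make_strong_table <- function(n_pairs = 100, seed = 1) {
  cfg <- thermophile_config(n_pairs = n_pairs, gene_length = 300, seed = seed)
  pd <- as_paired_dataset(generate_dataset(cfg))
  feature_table(pd, filter_significant(pd))
}

test_that("feature tables pool both classes over significant codons", {
  ft <- make_strong_table(n_pairs = 50, seed = 2)
  expect_s3_class(ft, "feature_table")
  expect_identical(nrow(ft), 100L)
  expect_identical(nlevels(ft$label), 2L)
  expect_true(all(grepl("^[ACGT]{3}$", setdiff(names(ft), "label"))))
  expect_false(anyNA(ft))
})

test_that("attribute weights hit the min-max endpoints", {
  # AAA separates the classes perfectly; AAC is pure noise; AAG constant
  set.seed(10)
  n <- 40
  me <- cbind(AAA = rnorm(n, 10, 0.5), AAC = runif(n, 2, 4),
              AAG = rep(5, n))
  mn <- cbind(AAA = rnorm(n, 2, 0.5), AAC = runif(n, 2, 4),
              AAG = rep(5, n))
  ft <- feature_table(paired_from_matrices(me, mn), c("AAA", "AAC", "AAG"))
  wm <- attribute_weights(ft)
  expect_true(all(wm >= 0 & wm <= 1))
  expect_true(all(wm["AAA", ] == 1))   # each algorithm's maximum
  expect_true(all(wm["AAG", ] == 0))   # constant feature
  expect_true(all(wm["AAA", ] > wm["AAC", ]))
})

test_that("the shifted codon outweighs null codons under every algorithm", {
  cfg <- gac_config(n_pairs = 100, gene_length = 300, seed = 13)
  pd <- as_paired_dataset(generate_dataset(cfg))
  ft <- feature_table(pd, c("GAC", "AAA", "CCC", "GGG", "TTT"))
  wm <- attribute_weights(ft)
  for (alg in colnames(wm)) {
    expect_true(all(wm["GAC", alg] > wm[c("AAA", "CCC", "GGG", "TTT"), alg]),
                info = alg)
  }
})

test_that("scale-free weights are invariant under affine feature rescaling", {
  ft <- make_strong_table(n_pairs = 40, seed = 6)
  wm1 <- attribute_weights(ft, algorithms = c("correlation", "infogain"))
  ft2 <- ft
  f <- setdiff(names(ft2), "label")[1]
  ft2[[f]] <- ft2[[f]] * 7 + 3
  wm2 <- attribute_weights(ft2, algorithms = c("correlation", "infogain"))
  expect_equal(wm1, wm2, tolerance = 1e-10)
})

test_that("plug-in weighters join the matrix after normalisation", {
  ft <- make_strong_table(n_pairs = 30, seed = 4)
  wm <- attribute_weights(ft, algorithms = "infogain",
                          custom = list(absdiff = function(x, y01) {
                            abs(colMeans(x[y01 == 1, ]) -
                                colMeans(x[y01 == 0, ]))
                          }))
  expect_true("absdiff" %in% colnames(wm))
  expect_true(all(wm[, "absdiff"] >= 0 & wm[, "absdiff"] <= 1))
})

test_that("support counts threshold the weight matrix per codon", {
  wm <- structure(matrix(c(0.9, 0.6, 0.4, 0.2, 0.1, 0), nrow = 2,
                         byrow = TRUE,
                         dimnames = list(c("AGG", "CAA"),
                                         c("a1", "a2", "a3"))),
                  class = c("weight_matrix", "matrix", "array"))
  sc <- support_counts(wm)
  expect_identical(sc$n_algorithms[sc$codon == "AGG"], 2L)
  expect_identical(sc$n_algorithms[sc$codon == "CAA"], 0L)
  expect_identical(support_counts(wm, threshold = 0)$n_algorithms, c(3L, 3L))
})

test_that("single-class tables are rejected", {
  ft <- make_strong_table(n_pairs = 10, seed = 3)
  ft1 <- ft[ft$label == levels(ft$label)[1], ]
  class(ft1) <- class(ft)
  expect_error(attribute_weights(ft1), "both classes")
})

test_that("accuracy is computed on held-out rows of a stratified split", {
  ft <- make_strong_table(n_pairs = 60, seed = 5)
  rep <- train_eval(ft, model = "knn", k = 10, train_frac = 0.7, seed = 9)
  expect_s3_class(rep, "classifier_report")
  expect_identical(rep$split$n_train + rep$split$n_test, nrow(ft))
  expect_equal(rep$split$n_train, round(0.7 * nrow(ft)))
  expect_true(rep$accuracy >= 0 && rep$accuracy <= 100)
  # determinism: same seed and inputs give the identical report
  rep2 <- train_eval(ft, model = "knn", k = 10, train_frac = 0.7, seed = 9)
  expect_identical(rep[c("accuracy", "split")], rep2[c("accuracy", "split")])
})

test_that("every model backend trains and predicts on the bias dataset", {
  ft <- make_strong_table(n_pairs = 60, seed = 12)
  for (m in c("knn", "nb", "logreg", "tree", "forest", "svm", "ann")) {
    rep <- train_eval(ft, model = m, seed = 2, ntree = 100)
    expect_true(rep$accuracy > 60, info = m)  # far above chance
  }
})

test_that("all four tree criteria grow usable trees", {
  ft <- make_strong_table(n_pairs = 80, seed = 14)
  for (cr in c("infogain", "gainratio", "gini", "accuracy")) {
    rep <- train_eval(ft, model = "tree", criterion = cr, seed = 2)
    expect_true(rep$accuracy > 60, info = cr)
    rules <- extract_rules(rep$fitted)
    expect_gt(length(rules), 0)
    expect_true(all(vapply(rules, function(r) nrow(r$conditions) >= 1,
                           logical(1))), info = cr)
  }
})

test_that("rule extraction mirrors the fitted tree structure", {
  ft <- make_strong_table(n_pairs = 100, seed = 15)
  rep <- train_eval(ft, model = "tree", criterion = "infogain", seed = 1)
  rules <- extract_rules(rep$fitted)
  # one rule per leaf
  expect_identical(length(rules), sum(rep$fitted$frame$var == "<leaf>"))
  # every rule's first condition names the root split feature
  root_var <- as.character(rep$fitted$frame$var[1])
  expect_true(all(vapply(rules, function(r) r$conditions$feature[1],
                         character(1)) == root_var))
  # each rule predicts one of the two class labels
  expect_true(all(vapply(rules, `[[`, character(1), "label") %in%
                  levels(ft$label)))
})

test_that("a depth-one tree renders two complementary rules", {
  # single perfectly separating feature forces a root-only split
  n <- 30
  me <- cbind(CAA = rep(1, n), GAC = rnorm(n, 10, 0.2))
  mn <- cbind(CAA = rep(1, n), GAC = rnorm(n, 2, 0.2))
  ft <- feature_table(paired_from_matrices(me, mn), c("CAA", "GAC"))
  rep <- train_eval(ft, model = "tree", criterion = "infogain", seed = 4,
                    minsplit = 5)
  rules <- extract_rules(rep$fitted)
  expect_identical(length(rules), 2L)
  cmps <- sort(vapply(rules, function(r) r$conditions$comparator[1],
                      character(1)))
  expect_identical(cmps, c("<=", ">"))
  expect_true(all(vapply(rules, function(r) r$conditions$feature[1],
                         character(1)) == "GAC"))
})

test_that("rendered rules follow the discrimination-rule grammar", {
  rules <- structure(list(
    list(conditions = data.frame(feature = "GAC", comparator = ">",
                                 threshold = 8.861), label = "Halophile"),
    list(conditions = data.frame(feature = c("GAC", "AGG"),
                                 comparator = c("<=", ">"),
                                 threshold = c(8.861, 1.441)),
         label = "Non-halophile")), class = "decision_rules")
  txt <- render_rules(rules, collapse = "; ")
  expect_identical(txt,
    "If % GAC (>8.861] → Halophile; If % GAC (≤8.861] and % AGG (>1.441] → Non-halophile")
})

test_that("a single-leaf tree yields an empty rule list with a warning", {
  # pure noise with a huge minsplit: rpart refuses to split
  set.seed(3)
  me <- cbind(AAA = rnorm(20))
  mn <- cbind(AAA = rnorm(20))
  ft <- feature_table(paired_from_matrices(me, mn), "AAA")
  rep <- train_eval(ft, model = "tree", criterion = "infogain", seed = 5,
                    minsplit = 1000)
  expect_warning(rules <- extract_rules(rep$fitted), "single leaf")
  expect_length(rules, 0)
})
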