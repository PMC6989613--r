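# Stratified node splits and edge hiding.

test_that("stratified split hits exact per-class counts on balanced labels", {
  g <- attributed_graph(matrix(0, 40, 40), matrix(rnorm(40), 40),
                        labels = rep(0:3, each = 10))
  ns <- split_nodes(g, 0.5, seed = 2)
  for (k in 0:3)
    expect_equal(sum(ns$train_mask[g$labels == k]), 5L)
  expect_false(any(ns$train_mask & ns$test_mask))
  expect_true(all(xor(ns$train_mask, ns$test_mask)))
})

test_that("train size matches round(ratio * n_labeled)", {
  g <- attributed_graph(matrix(0, 100, 100), matrix(rnorm(100), 100),
                        labels = rep(0:4, each = 20))
  ns <- split_nodes(g, 0.9, seed = 7)
  expect_equal(sum(ns$train_mask), 90L)
})

test_that("per-class train proportions stay within rounding of the ratio", {
  for (s in 1:5) {
    set.seed(s)
    lab <- sample(0:3, 120, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    g <- attributed_graph(matrix(0, 120, 120), matrix(rnorm(120), 120), labels = lab)
    ratio <- c(0.3, 0.55, 0.7)[(s %% 3) + 1]
    ns <- split_nodes(g, ratio, seed = s)
    for (k in 0:3) {
      nk <- sum(lab == k)
      got <- sum(ns$train_mask[lab == k])
      expect_lte(abs(got - ratio * nk), 1 + 1e-9)
    }
  }
})

test_that("unlabeled nodes never appear in either mask", {
  lab <- c(rep(0:1, each = 10), rep(NA_integer_, 5))
  g <- attributed_graph(matrix(0, 25, 25), matrix(rnorm(25), 25), labels = lab)
  ns <- split_nodes(g, 0.5, seed = 1)
  expect_false(any(ns$train_mask[is.na(lab)]))
  expect_false(any(ns$test_mask[is.na(lab)]))
})

test_that("hide_edges partitions the edge set and balances negatives", {
  g <- tiny_graph(seed = 8, n = 60, classes = 3, p_in = 0.4, p_out = 0.05)
  m <- Matrix::nnzero(g$A) / 2
  es <- hide_edges(g, val_frac = 0.1, test_frac = 0.2, seed = 3)
  expect_equal(nrow(es$pos_test), floor(0.2 * m))
  expect_equal(nrow(es$pos_val), floor(0.1 * m))
  expect_equal(nrow(es$neg_test), nrow(es$pos_test))
  expect_equal(nrow(es$neg_val), nrow(es$pos_val))
  expect_true(Matrix::isSymmetric(es$A_train))

  key <- function(M) paste(pmin(M[, 1], M[, 2]), pmax(M[, 1], M[, 2]))
  E0 <- mtgnn:::edge_list(g$A)
  Etr <- mtgnn:::edge_list(es$A_train)
  parts <- c(key(Etr), key(es$pos_val), key(es$pos_test))
  expect_equal(sort(parts), sort(key(E0)))     # exact partition
  expect_equal(anyDuplicated(parts), 0L)

  A <- as.matrix(g$A)
  for (nm in c("pos_val", "pos_test"))
    expect_true(all(A[es[[nm]]] == 1))
  for (nm in c("neg_val", "neg_test"))
    expect_true(all(A[es[[nm]]] == 0))
  # hidden positives are truly absent from the training adjacency
  Atr <- as.matrix(es$A_train)
  expect_true(all(Atr[rbind(es$pos_val, es$pos_test)] == 0))
})

test_that("zero fractions leave the adjacency untouched", {
  g <- tiny_graph(seed = 3, n = 20)
  es <- hide_edges(g, 0, 0, seed = 1)
  expect_identical(as.matrix(es$A_train), as.matrix(g$A))
  expect_equal(nrow(es$pos_test), 0L)
})

test_that("degenerate edge splits are refused", {
  g <- attributed_graph(rbind(c(0, 1), c(1, 0)), matrix(1:2, 2))
  expect_error(hide_edges(g, 0, 0.5, seed = 1), "fewer than 5 edges")
  g2 <- tiny_graph(seed = 1, n = 20)
  expect_error(hide_edges(g2, 0.6, 0.5, seed = 1), "val_frac")
})

test_that("negative pairs are verified non-adjacent and exhaustive when forced", {
  g <- tiny_graph(seed = 4, n = 30, p_in = 0.5, p_out = 0.1)
  A <- as.matrix(g$A)
  np <- sample_negative_pairs(g, 40, seed = 5)
  expect_equal(nrow(np), 40L)
  expect_true(all(A[np] == 0))
  expect_true(all(np[, 1] < np[, 2]))
  expect_equal(anyDuplicated(paste(np[, 1], np[, 2])), 0L)

  empty4 <- attributed_graph(matrix(0, 4, 4), matrix(1:4, 4))
  all6 <- sample_negative_pairs(empty4, 6, seed = 1)
  expect_equal(nrow(unique(all6)), 6L)

  K4 <- attributed_graph(matrix(1, 4, 4) - diag(4), matrix(1:4, 4))
  expect_error(sample_negative_pairs(K4, 1, seed = 1), "more negative pairs")
})

test_that("the exclude set is honored", {
  empty4 <- attributed_graph(matrix(0, 4, 4), matrix(1:4, 4))
  excl <- cbind(c(1, 1, 1), c(2, 3, 4))
  np <- sample_negative_pairs(empty4, 3, exclude = excl, seed = 2)
  expect_true(all(np[, 1] != 1))
})

test_that("splits are deterministic given their seed", {
  g <- tiny_graph(seed = 2, n = 40, p_in = 0.4)
  expect_identical(split_nodes(g, 0.4, seed = 9), split_nodes(g, 0.4, seed = 9))
  e1 <- hide_edges(g, 0.05, 0.1, seed = 9)
  e2 <- hide_edges(g, 0.05, 0.1, seed = 9)
  expect_identical(e1$pos_test, e2$pos_test)
  expect_identical(e1$neg_test, e2$neg_test)
  expect_identical(as.matrix(e1$A_train), as.matrix(e2$A_train))
})

test_that("split serialization writes masks, pair lists and a seed sidecar", {
  g <- tiny_graph(seed = 2, n = 40, p_in = 0.4)
  ns <- split_nodes(g, 0.4, seed = 9)
  es <- hide_edges(g, 0.05, 0.1, seed = 9)
  d <- withr::local_tempdir()
  paths <- write_splits(ns, es, g, d)
  expect_true(all(file.exists(paths)))
  meta <- yaml::read_yaml(file.path(d, "splits.yaml"))
  expect_equal(meta$node_split$seed, 9L)
  tab <- read.delim(file.path(d, "node_split.tsv"))
  expect_equal(sum(tab$split == "train"), sum(ns$train_mask))
})
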