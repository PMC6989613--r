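# Metrics against brute-force oracles, plus the experiment drivers.

test_that("accuracy counts masked agreements exactly", {
  expect_equal(accuracy(c(0L, 1L, 2L), c(0L, 1L, 2L), rep(TRUE, 3)), 1)
  expect_equal(accuracy(c(1L, 2L, 0L), c(0L, 1L, 2L), rep(TRUE, 3)), 0)
  set.seed(3)
  for (r in 1:10) {
    pred <- sample(0:2, 30, TRUE); true <- sample(0:2, 30, TRUE)
    mask <- runif(30) < 0.5
    if (!any(mask)) mask[1] <- TRUE
    expect_equal(accuracy(pred, true, mask),
                 sum(pred[mask] == true[mask]) / sum(mask))
  }
  expect_error(accuracy(1L, 1L, FALSE), "no nodes")
})

test_that("roc_auc hits its extreme and all-tie values", {
  expect_equal(roc_auc(c(3, 4), c(1, 2)), 1)
  expect_equal(roc_auc(c(1, 2), c(3, 4)), 0)
  expect_equal(roc_auc(rep(1, 5), rep(1, 7)), 0.5)
  expect_error(roc_auc(numeric(0), 1), "nonempty")
})

test_that("roc_auc equals the brute-force pairwise count, ties included", {
  set.seed(4)
  for (r in 1:30) {
    np <- sample(2:40, 1); nn <- sample(2:40, 1)
    # coarse grid forces many ties
    pos <- sample(seq(0, 1, 0.1), np, TRUE) + sample(c(0, 0.5), np, TRUE)
    neg <- sample(seq(0, 1, 0.1), nn, TRUE)
    expect_equal(roc_auc(pos, neg), auc_oracle(pos, neg), tolerance = 1e-12)
  }
})

test_that("roc_auc is invariant under strictly monotone score transforms", {
  set.seed(5)
  pos <- rnorm(25, 1); neg <- rnorm(25)
  a0 <- roc_auc(pos, neg)
  expect_equal(roc_auc(exp(pos), exp(neg)), a0)
  expect_equal(roc_auc(atan(pos) * 3 + 2, atan(neg) * 3 + 2), a0)
})

test_that("average precision matches hand enumeration and the rank oracle", {
  expect_equal(average_precision(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
  # ranking pos, neg, pos, neg -> (1/1 + 2/3)/2
  expect_equal(average_precision(c(4, 3, 2, 1), c(1, 0, 1, 0)), 5 / 6)
  set.seed(6)
  for (r in 1:30) {
    n <- sample(5:60, 1)
    scores <- sample(seq(0, 2, 0.25), n, TRUE)
    targets <- rbinom(n, 1, 0.4)
    if (!any(targets == 1)) targets[1] <- 1L
    expect_equal(average_precision(scores, targets),
                 ap_oracle(scores, targets), tolerance = 1e-12)
  }
  expect_error(average_precision(1:3, c(0, 0, 0)), "no positive")
})

test_that("evaluate_model is deterministic and composes the three metrics", {
  g <- tiny_graph(seed = 10, n = 50, classes = 2, p_in = 0.4, p_out = 0.05,
                  F = 5, mu = 2)
  ns <- split_nodes(g, 0.5, seed = 10)
  es <- hide_edges(g, 0, 0.15, seed = 10)
  enc <- encoder_config("gcn", layer_dims = c(4L, 6L), dropout = 0.1)
  tc <- train_config(epochs = 15L, seed = 10, eval_every = 0L)
  f <- fit(g, ns, es, enc, tc)
  r1 <- evaluate_model(f, g, ns, es)
  r2 <- evaluate_model(f$params, g, ns, es, enc)
  expect_identical(r1, r2)
  expect_true(all(unlist(r1[c("accuracy", "auc", "ap")]) >= 0))
  expect_true(all(unlist(r1[c("accuracy", "auc", "ap")]) <= 1))

  # recompute from raw scores with the metric ops directly
  H <- encode(es$A_train, g$Z, enc, f$params$encoder)
  P <- class_probabilities(H, f$params$clf)
  pred <- apply(P, 1, which.max) - 1L
  expect_equal(r1$accuracy, accuracy(pred, g$labels, ns$test_mask))
  sp <- vapply(seq_len(nrow(es$pos_test)), function(i)
    link_score(H[es$pos_test[i, 1], ], H[es$pos_test[i, 2], ], f$params$dec),
    numeric(1))
  sn <- vapply(seq_len(nrow(es$neg_test)), function(i)
    link_score(H[es$neg_test[i, 1], ], H[es$neg_test[i, 2], ], f$params$dec),
    numeric(1))
  expect_equal(r1$auc, roc_auc(sp, sn), tolerance = 1e-12)
  expect_equal(r1$ap, average_precision(c(sp, sn),
                                        rep(1:0, c(length(sp), length(sn)))),
               tolerance = 1e-12)
})

test_that("an untrained decoder on random embeddings scores near-chance AUC", {
  set.seed(11)
  aucs <- replicate(20, {
    H <- matrix(rnorm(40 * 6), 40, 6)
    dec <- link_decoder("bilinear", M = matrix(rnorm(36, sd = 0.5), 6), b = 0)
    pos <- cbind(sample(40, 15, TRUE), sample(40, 15, TRUE))
    neg <- cbind(sample(40, 15, TRUE), sample(40, 15, TRUE))
    roc_auc(mtgnn:::pair_scores(H, dec, pos), mtgnn:::pair_scores(H, dec, neg))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("the alpha sweep produces one deterministic row per alpha", {
  g <- tiny_graph(seed = 20, n = 50, classes = 2, p_in = 0.4, p_out = 0.05,
                  F = 5, mu = 2)
  enc <- encoder_config("gcn", layer_dims = c(4L, 6L), dropout = 0.1)
  tc <- train_config(epochs = 10L, seed = 20, eval_every = 0L)
  tab1 <- alpha_sweep(g, enc, tc, alphas = c(0, 0.5, 1), repeats = 2L,
                      train_ratio = 0.5, val_frac = 0, test_frac = 0.15)
  expect_equal(nrow(tab1), 3L)
  expect_equal(tab1$alpha, c(0, 0.5, 1))
  expect_equal(tab1$repeats, rep(2L, 3))
  expect_equal(nrow(attr(tab1, "runs")), 6L)
  tab2 <- alpha_sweep(g, enc, tc, alphas = c(0, 0.5, 1), repeats = 2L,
                      train_ratio = 0.5, val_frac = 0, test_frac = 0.15)
  expect_identical(tab1, tab2)
  expect_true(all(tab1$mean_auc >= 0 & tab1$mean_auc <= 1))
})

test_that("the default alpha grid covers 0 to 1 in eleven steps", {
  expect_equal(eval(formals(alpha_sweep)$alphas), seq(0, 1, by = 0.1))
})

test_that("the ratio sweep loops over the label-ratio grid", {
  g <- tiny_graph(seed = 21, n = 60, classes = 2, p_in = 0.4, p_out = 0.05,
                  F = 5, mu = 2)
  enc <- encoder_config("gcn", layer_dims = c(3L, 4L), dropout = 0)
  tc <- train_config(epochs = 8L, seed = 21, eval_every = 0L)
  tab <- ratio_sweep(g, enc, tc, ratios = c(0.2, 0.5, 0.8), repeats = 2L,
                     val_frac = 0, test_frac = 0.15)
  expect_equal(tab$train_ratio, c(0.2, 0.5, 0.8))
  expect_equal(eval(formals(ratio_sweep)$ratios), seq(0.1, 0.9, by = 0.1))
})
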