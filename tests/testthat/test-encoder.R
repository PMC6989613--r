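# Attention primitives and encoder layers against dense references.

test_that("attention logits follow the LeakyReLU-of-dot-product definition", {
  expect_equal(attention_logits(c(1, 2), c(3, 4), rep(0, 4)), 0)
  # pre-activation of exactly -1 with slope 0.2
  expect_equal(attention_logits(1, 0, c(-1, 5), leaky_slope = 0.2), -0.2)
  # hand-expanded 1-dim case
  a <- c(0.3, -0.7); wi <- 1.5; wj <- -2
  pre <- 0.3 * 1.5 + (-0.7) * (-2)
  expect_equal(attention_logits(wi, wj, a), pre)  # positive branch
  expect_error(attention_logits(c(1, 2), 1, rep(0, 4)), "equal width")
})

test_that("normalized attention is a stable softmax over the neighborhood", {
  expect_equal(normalize_attention(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(normalize_attention(c(log(2), 0)), c(2 / 3, 1 / 3))
  set.seed(1)
  for (r in 1:20) {
    l <- rnorm(5, sd = 3)
    direct <- exp(l) / sum(exp(l))
    expect_equal(normalize_attention(l), direct, tolerance = 1e-12)
    expect_equal(sum(normalize_attention(l)), 1, tolerance = 1e-12)
  }
  # huge logits do not overflow
  expect_equal(sum(normalize_attention(c(1e4, 1e4 - 2))), 1)
  expect_error(normalize_attention(numeric(0)), "empty")
})

test_that("an isolated node's attention output is sigma(W h_i)", {
  A_loop <- diag(3)
  A_loop[1, 2] <- A_loop[2, 1] <- 1
  H <- matrix(c(1, -1, 2, 0.5, 0, -2), 3, 2)
  W <- matrix(c(0.5, -0.2, 1, 0.3), 2, 2)
  a <- c(0.1, 0.2, -0.3, 0.4)
  out <- gat_layer(H, A_loop, W, a, activation = "identity", merge = "mean")
  expect_equal(out[3, ], drop(W %*% H[3, ]), tolerance = 1e-12)
})

test_that("identical node features give identical attention outputs", {
  g <- tiny_graph(seed = 3, n = 8)
  A_loop <- as.matrix(g$A) + diag(8)
  H <- matrix(rep(c(1, 2, 3), each = 8), 8, 3)
  W <- matrix(rnorm(6), 2, 3)
  a <- rnorm(4)
  out <- gat_layer(H, A_loop, W, a)
  expect_equal(max(apply(out, 2, function(x) diff(range(x)))), 0, tolerance = 1e-12)
})

test_that("gat_layer matches the dense masked-softmax reference on random graphs", {
  set.seed(77)
  for (r in 1:25) {
    n <- sample(3:12, 1)
    g <- tiny_graph(seed = 100 + r, n = n, classes = 2, F = 3)
    A_loop <- as.matrix(g$A) + diag(n)
    H <- matrix(rnorm(n * 3), n, 3)
    K <- sample(1:3, 1)
    W <- replicate(K, matrix(rnorm(2 * 3, sd = 0.8), 2, 3), simplify = FALSE)
    a <- replicate(K, rnorm(4), simplify = FALSE)
    for (merge in c("concat", "mean")) {
      got <- gat_layer(H, A_loop, W, a, merge = merge, activation = "elu")
      want <- gat_layer_dense_oracle(H, A_loop, W, a, merge = merge,
                                     activation = "elu")
      expect_equal(got, want, tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("gcn_layer reproduces the hand-computed two-node propagation", {
  A <- rbind(c(0, 1), c(1, 0))
  Ahat <- normalized_adjacency(A)
  expect_equal(Ahat, matrix(0.5, 2, 2), ignore_attr = TRUE)
  H <- diag(2)
  out <- gcn_layer(H, Ahat, diag(2), activation = "identity")
  expect_equal(out, matrix(0.5, 2, 2), ignore_attr = TRUE)
  # single node: A_hat = [[1]]
  out1 <- gcn_layer(matrix(2), matrix(1), matrix(3), activation = "identity")
  expect_equal(out1[1, 1], 6)
})

test_that("gcn_layer matches the dense reference and is permutation equivariant", {
  set.seed(11)
  for (r in 1:25) {
    n <- sample(3:12, 1)
    g <- tiny_graph(seed = 200 + r, n = n, classes = 2, F = 4)
    A <- as.matrix(g$A)
    H <- matrix(rnorm(n * 4), n, 4)
    W <- matrix(rnorm(3 * 4), 3, 4)
    got <- gcn_layer(H, normalized_adjacency(A), W, activation = "elu")
    want <- gcn_layer_dense_oracle(H, A, W, activation = "elu")
    expect_equal(got, want, tolerance = 1e-8, ignore_attr = TRUE)

    p <- sample(n)
    got_p <- gcn_layer(H[p, ], normalized_adjacency(A[p, p]), W, activation = "elu")
    expect_equal(got_p, got[p, ], tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("encode stacks layers exactly as explicit layer composition", {
  g <- tiny_graph(seed = 31, n = 5, classes = 2, F = 3, p_in = 0.8, p_out = 0.3)
  enc <- encoder_config("gat", layer_dims = c(2L, 3L), heads = c(2L, 1L), dropout = 0)
  params <- init_params(enc, 3L, 2L, seed = 9)$encoder
  H <- encode(g$A, g$Z, enc, params)
  expect_equal(dim(H), c(5L, 3L))

  A_loop <- as.matrix(g$A) + diag(5)
  H1 <- gat_layer(g$Z, A_loop, params[[1]]$W, params[[1]]$a,
                  activation = "elu", merge = "concat")
  H2 <- gat_layer(H1, A_loop, params[[2]]$W, params[[2]]$a,
                  activation = "identity", merge = "mean")
  expect_equal(H, H2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero-weight convolutional encoder maps everything to zero", {
  g <- tiny_graph(seed = 12, n = 10, classes = 2)
  enc <- encoder_config("gcn", layer_dims = c(3L, 2L), dropout = 0)
  params <- init_params(enc, ncol(g$Z), 2L, seed = 1)$encoder
  params[[1]]$W[] <- 0
  params[[2]]$W[] <- 0
  H <- encode(g$A, g$Z, enc, params)
  expect_equal(H, matrix(0, 10, 2), ignore_attr = TRUE)
})

test_that("encode without training mode is deterministic despite nonzero dropout config", {
  g <- tiny_graph(seed = 13, n = 15, classes = 3)
  enc <- encoder_config("gat", dropout = 0.5)
  params <- init_params(enc, ncol(g$Z), 3L, seed = 2)$encoder
  set.seed(1); H1 <- encode(g$A, g$Z, enc, params)
  set.seed(2); H2 <- encode(g$A, g$Z, enc, params)
  expect_identical(H1, H2)
  expect_equal(dim(H1), c(15L, 64L))
})

test_that("internal attention coefficients sum to one over every neighborhood", {
  g <- tiny_graph(seed = 14, n = 20, classes = 2)
  gp <- mtgnn:::prep_gat_graph(g$A)
  W <- matrix(rnorm(8), 2, 4)
  a <- rnorm(4)
  hf <- mtgnn:::gat_head_forward(g$Z, W, a, 0.2, gp)
  sums <- rowsum(cbind(hf$alpha), gp$ei)[, 1]
  expect_equal(sums, rep(1, 20), tolerance = 1e-9, ignore_attr = TRUE)
})
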