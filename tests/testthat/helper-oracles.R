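# Independent reference implementations used as oracles. These are written
# naively (explicit loops, dense matrices) and must stay independent of the
# package's fast paths.

# Small attributed graph fixtures -------------------------------------------

tiny_graph <- function(seed = 1, n = 12, classes = 3, p_in = 0.7, p_out = 0.2,
                       F = 4, mu = 1.5, sigma_f = 0.5) {
  make_synthetic_dataset(sbm_config(n = n, classes = classes, p_in = p_in,
                                    p_out = p_out, F = F, mu = mu,
                                    sigma_f = sigma_f, seed = seed))
}

# Dense masked-attention reference for one GAT layer -------------------------

leaky_ref <- function(x, slope) ifelse(x > 0, x, slope * x)
elu_ref <- function(x) ifelse(x > 0, x, exp(x) - 1)

gat_layer_dense_oracle <- function(H, A_loop, W_list, a_list, slope = 0.2,
                                   activation = "elu", merge = "concat") {
  A_loop <- as.matrix(A_loop)
  n <- nrow(A_loop)
  outs <- lapply(seq_along(W_list), function(k) {
    W <- W_list[[k]]; a <- a_list[[k]]
    HW <- H %*% t(W)
    E <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (A_loop[i, j] != 0)
        E[i, j] <- leaky_ref(sum(a * c(HW[i, ], HW[j, ])), slope)
    }
    Alpha <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- which(!is.na(E[i, ]))
      ex <- exp(E[i, nb] - max(E[i, nb]))
      Alpha[i, nb] <- ex / sum(ex)
    }
    O <- Alpha %*% HW
    if (activation == "elu") elu_ref(O) else O
  })
  if (merge == "concat") do.call(cbind, outs)
  else Reduce(`+`, outs) / length(outs)
}

gcn_layer_dense_oracle <- function(H, A, W, activation = "identity") {
  n <- nrow(as.matrix(A))
  AI <- as.matrix(A) + diag(n)
  D <- rowSums(AI)
  Ahat <- diag(1 / sqrt(D)) %*% AI %*% diag(1 / sqrt(D))
  O <- Ahat %*% H %*% t(W)
  if (activation == "elu") elu_ref(O) else O
}

# Brute-force metrics --------------------------------------------------------

auc_oracle <- function(pos, neg) {
  conc <- 0; ties <- 0
  for (p in pos) for (q in neg) {
    if (p > q) conc <- conc + 1 else if (p == q) ties <- ties + 1
  }
  (conc + 0.5 * ties) / (length(pos) * length(neg))
}

ap_oracle <- function(scores, targets) {
  ord <- order(-scores)
  s <- targets[ord]
  ranks <- which(s == 1)
  mean(vapply(ranks, function(r) sum(s[seq_len(r)]) / r, numeric(1)))
}

# Literal double-sum losses ---------------------------------------------------

nc_loss_oracle <- function(P, labels, mask) {
  tot <- 0; cnt <- 0
  for (v in which(mask)) {
    for (k in seq_len(ncol(P))) {
      y <- as.numeric(labels[v] == (k - 1))
      tot <- tot - y * log(max(P[v, k], 1e-12))
    }
    cnt <- cnt + 1
  }
  tot / cnt
}

lp_loss_oracle <- function(H, decoder, pos, neg) {
  tot <- 0
  for (r in seq_len(nrow(pos))) {
    s <- link_score(H[pos[r, 1], ], H[pos[r, 2], ], decoder)
    tot <- tot - log(max(s, 1e-12))
  }
  for (r in seq_len(nrow(neg))) {
    s <- link_score(H[neg[r, 1], ], H[neg[r, 2], ], decoder)
    tot <- tot - log(max(1 - s, 1e-12))
  }
  tot / (nrow(pos) + nrow(neg))
}

# Central finite differences of the joint loss --------------------------------

numeric_joint_gradient <- function(params, batch, enc_config, alpha, h = 1e-5) {
  pv <- mtgnn:::flatten_params(params)
  lossfun <- function(v) {
    p <- mtgnn:::unflatten_params(v, params)
    mtgnn:::model_forward(p, batch, enc_config, alpha, train_mode = FALSE)$loss$L
  }
  vapply(seq_along(pv), function(i) {
    vp <- pv; vp[i] <- vp[i] + h
    vm <- pv; vm[i] <- vm[i] - h
    (lossfun(vp) - lossfun(vm)) / (2 * h)
  }, numeric(1))
}
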