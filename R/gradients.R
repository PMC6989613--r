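# Reverse-mode gradients for the joint objective L = L_NC + alpha * L_LP.
#
# The forward pass records per-layer caches (transformed features, attention
# logits/coefficients, dropout masks); the backward pass walks the heads and
# layers in reverse. Everything is dense linear algebra except attention,
# which stays on the directed edge list. Correctness is pinned by the
# finite-difference tests.

# Scatter-add rows of x into an n-row accumulator by group index.
scatter_rows <- function(x, group, n, acc = NULL) {
  if (is.null(acc)) acc <- matrix(0, n, ncol(x))
  s <- rowsum(x, group)
  rows <- as.integer(rownames(s))
  acc[rows, ] <- acc[rows, , drop = FALSE] + s
  acc
}

group_sums <- function(x, group) rowsum(cbind(x), group)[, 1L]

# ---- model forward ---------------------------------------------------------

# batch: list(Z, n, prep, labels, train_mask, lp)
# lp: list(mode = "exact", A_dense, ut) or list(mode = "pairs", pos, neg)
#     or list(mode = "sampled", pos, Ad) where negatives are drawn per call.
model_forward <- function(params, batch, enc_config, alpha, train_mode = FALSE) {
  enc <- encoder_forward(batch$Z, params$encoder, enc_config, batch$prep,
                         train_mode)
  H <- enc$H
  P <- class_probabilities(H, params$clf)
  l_nc <- nc_loss(P, batch$labels, batch$train_mask)

  lp <- batch$lp
  lp_cache <- NULL
  if (lp$mode == "exact") {
    Q <- lp_logits_dense(H, params$dec)
    S <- sigmoid(Q[lp$ut])
    t <- lp$A_dense[lp$ut]
    l_lp <- mean(-(t * log(pmax(S, LOG_EPS)) + (1 - t) * log(pmax(1 - S, LOG_EPS))))
    lp_cache <- list(S = S, t = t)
  } else {
    if (lp$mode == "sampled") {
      neg <- sample_nonedge_pairs_fast(lp$Ad, nrow(lp$pos))
      pos <- lp$pos
    } else {
      pos <- lp$pos; neg <- lp$neg
    }
    s_pos <- pair_scores(H, params$dec, pos)
    s_neg <- pair_scores(H, params$dec, neg)
    npair <- nrow(pos) + nrow(neg)
    l_lp <- (-sum(log(pmax(s_pos, LOG_EPS))) -
              sum(log(pmax(1 - s_neg, LOG_EPS)))) / npair
    lp_cache <- list(pos = pos, neg = neg, s_pos = s_pos, s_neg = s_neg)
  }
  list(loss = total_loss(l_nc, l_lp, alpha),
       cache = list(enc = enc, H = H, P = P, lp = lp_cache))
}

# Uniform non-edge sampler by rejection against a dense 0/1 adjacency.
sample_nonedge_pairs_fast <- function(Ad, k) {
  n <- nrow(Ad)
  out_i <- integer(0); out_j <- integer(0)
  while (length(out_i) < k) {
    need <- 2L * (k - length(out_i)) + 8L
    i <- sample.int(n, need, replace = TRUE)
    j <- sample.int(n, need, replace = TRUE)
    ok <- i != j & Ad[cbind(i, j)] == 0
    out_i <- c(out_i, i[ok]); out_j <- c(out_j, j[ok])
  }
  cbind(i = out_i[seq_len(k)], j = out_j[seq_len(k)])
}

# ---- model backward --------------------------------------------------------

model_backward <- function(params, batch, enc_config, alpha, cache) {
  H <- cache$H
  n <- batch$n
  d <- ncol(H)

  # classifier branch
  idx <- which(batch$train_mask)
  n_mask <- length(idx)
  cmat <- ncol(cache$P)
  dLogits <- matrix(0, n, cmat)
  Y <- matrix(0, n_mask, cmat)
  Y[cbind(seq_len(n_mask), batch$labels[idx] + 1L)] <- 1
  dLogits[idx, ] <- (cache$P[idx, , drop = FALSE] - Y) / n_mask
  g_clf <- list(W = crossprod(H, dLogits), b = colSums(dLogits))
  dH <- dLogits %*% t(params$clf$W)

  # link branch
  bilinear <- params$dec$kind == "bilinear"
  if (bilinear) {
    Ms <- (params$dec$M + t(params$dec$M)) / 2
    g_dec <- list(M = matrix(0, d, d), b = 0)
  } else {
    g_dec <- list()
  }
  if (alpha > 0) {
    lpc <- cache$lp
    if (batch$lp$mode == "exact") {
      npairs <- length(lpc$S)
      gv <- (lpc$S - lpc$t) / npairs
      G <- matrix(0, n, n)
      G[batch$lp$ut] <- gv
      Gs <- G + t(G)
      if (bilinear) {
        HM <- H %*% Ms
        dH_lp <- Gs %*% HM
        dMsym <- crossprod(H, G %*% H)
        g_dec$M <- (dMsym + t(dMsym)) / 2
        g_dec$b <- sum(gv)
      } else {
        dH_lp <- Gs %*% H
      }
    } else {
      pos <- lpc$pos; neg <- lpc$neg
      npairs <- nrow(pos) + nrow(neg)
      gv <- c(lpc$s_pos - 1, lpc$s_neg) / npairs
      pi <- c(pos[, 1L], neg[, 1L]); pj <- c(pos[, 2L], neg[, 2L])
      B <- if (bilinear) H %*% Ms else H
      dH_lp <- scatter_rows(gv * B[pj, , drop = FALSE], pi, n)
      dH_lp <- scatter_rows(gv * B[pi, , drop = FALSE], pj, n, dH_lp)
      if (bilinear) {
        dMsym <- crossprod(H[pi, , drop = FALSE], gv * H[pj, , drop = FALSE])
        g_dec$M <- (dMsym + t(dMsym)) / 2
        g_dec$b <- sum(gv)
      }
    }
    dH <- dH + alpha * dH_lp
    if (bilinear) {
      g_dec$M <- alpha * g_dec$M
      g_dec$b <- alpha * g_dec$b
    }
  }

  # encoder
  g_enc <- encoder_backward(dH, params$encoder, enc_config, batch$prep,
                            cache$enc$caches)
  list(encoder = g_enc, clf = g_clf, dec = g_dec)
}

encoder_backward <- function(dH, enc_params, config, prep, caches) {
  L <- length(config$layer_dims)
  grads <- vector("list", L)
  dOut <- dH
  for (l in rev(seq_len(L))) {
    if (config$kind == "gat") {
      bk <- gat_layer_backward(dOut, enc_params[[l]], caches[[l]], prep$gp,
                               config$leaky_slope)
    } else {
      bk <- gcn_layer_backward(dOut, enc_params[[l]]$W, caches[[l]], prep$A_hat)
    }
    grads[[l]] <- bk$grads
    dOut <- bk$dH_in
  }
  grads
}

gat_layer_backward <- function(dOut, layer_params, cache, gp, slope) {
  K <- length(layer_params$W)
  Fp <- nrow(layer_params$W[[1L]])
  H_use <- cache$H_use
  n <- nrow(H_use)
  dH_use <- matrix(0, n, ncol(H_use))
  gW <- vector("list", K); ga <- vector("list", K)
  for (k in seq_len(K)) {
    hd <- cache$heads[[k]]
    dOut_h <- if (cache$merge == "concat")
      dOut[, (k - 1L) * Fp + seq_len(Fp), drop = FALSE]
    else dOut / K
    dPre <- if (cache$activation == "elu") dOut_h * elu_grad(hd$out_pre) else dOut_h

    HW <- hd$HW
    dAlpha_used <- rowSums(dPre[gp$ei, , drop = FALSE] * HW[gp$ej, , drop = FALSE])
    dHW <- scatter_rows(hd$alpha_used * dPre[gp$ei, , drop = FALSE], gp$ej, n)
    dAlpha <- if (!is.null(hd$attn_keep))
      dAlpha_used * hd$attn_keep / (1 - cache$dropout)
    else dAlpha_used
    sdot <- group_sums(hd$alpha * dAlpha, gp$ei)
    dE <- hd$alpha * (dAlpha - sdot[gp$ei])
    dPreE <- dE * leaky_relu_grad(hd$pre_e, slope)
    ds <- group_sums(dPreE, gp$ei)
    dd <- group_sums(dPreE, gp$ej)
    a <- layer_params$a[[k]]
    a1 <- a[seq_len(Fp)]; a2 <- a[Fp + seq_len(Fp)]
    dHW <- dHW + outer(ds, a1) + outer(dd, a2)
    ga[[k]] <- c(drop(crossprod(HW, ds)), drop(crossprod(HW, dd)))
    gW[[k]] <- crossprod(dHW, H_use)
    dH_use <- dH_use + dHW %*% layer_params$W[[k]]
  }
  dH_in <- if (!is.null(cache$in_keep))
    dH_use * cache$in_keep / (1 - cache$dropout)
  else dH_use
  list(grads = list(W = gW, a = ga), dH_in = dH_in)
}

gcn_layer_backward <- function(dOut, W, cache, A_hat) {
  dPre <- if (cache$activation == "elu") dOut * elu_grad(cache$pre) else dOut
  gW <- crossprod(dPre, cache$X)
  dX <- dPre %*% W
  dH_use <- as.matrix(A_hat %*% dX)
  dH_in <- if (!is.null(cache$in_keep))
    dH_use * cache$in_keep / (1 - cache$dropout)
  else dH_use
  list(grads = list(W = gW), dH_in = dH_in)
}
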