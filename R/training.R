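# Joint full-batch optimization of encoder + task heads.
#
# Recipe defaults follow the transductive GAT lineage: Adam at a fixed
# learning rate of 0.005, 300 epochs, dropout 0.1 at two sites (layer inputs
# and attention coefficients), 8 attention heads, tradeoff weight alpha = 1,
# no early stopping. All randomness (initialization, dropout, negative
# sampling) flows from one master seed through fixed sub-seeds.

#' Training configuration
#'
#' @param lr Learning rate (> 0).
#' @param epochs Number of full-batch epochs (>= 1).
#' @param alpha Tradeoff weight on the link-prediction loss (>= 0).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param seed Master seed for initialization and the training-time RNG
#'   stream.
#' @param weight_init Initialization scheme; only `"glorot-uniform"` is
#'   implemented.
#' @param log_every Epoch interval for progress messages (0 = silent).
#' @param eval_every Epoch interval at which validation metrics (held-out
#'   accuracy, validation-edge AUC) are computed into the history; other rows
#'   hold `NA`. 0 disables per-epoch evaluation.
#' @param decoder Link decoder kind, `"bilinear"` (default) or `"inner"`.
#' @param lp_mode Link-loss evaluation mode: `"exact"` scores every unordered
#'   non-self pair against the training adjacency, `"sampled"` uses the
#'   training edges plus one freshly drawn non-edge per edge per epoch,
#'   `"auto"` (default) picks exact up to `lp_exact_max_n` nodes.
#' @param lp_exact_max_n Node-count threshold for `lp_mode = "auto"`.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 0.005, epochs = 300L, alpha = 1.0,
                         optimizer = c("adam", "sgd"), seed = 1L,
                         weight_init = "glorot-uniform", log_every = 0L,
                         eval_every = 10L, decoder = c("bilinear", "inner"),
                         lp_mode = c("auto", "exact", "sampled"),
                         lp_exact_max_n = 3000L) {
  optimizer <- match.arg(optimizer)
  decoder <- match.arg(decoder)
  lp_mode <- match.arg(lp_mode)
  if (lr < 0) stop("lr must be >= 0", call. = FALSE)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (weight_init != "glorot-uniform")
    stop("unsupported weight_init: ", weight_init, call. = FALSE)
  structure(list(lr = lr, epochs = as.integer(epochs), alpha = alpha,
                 optimizer = optimizer, seed = as.integer(seed),
                 weight_init = weight_init, log_every = as.integer(log_every),
                 eval_every = as.integer(eval_every), decoder = decoder,
                 lp_mode = lp_mode, lp_exact_max_n = as.integer(lp_exact_max_n)),
            class = "train_config")
}

#' Initialize model parameters
#'
#' Glorot-uniform weights (`limit = sqrt(6 / (fan_in + fan_out))`) and zero
#' biases for the encoder layers, the softmax classifier head and, for the
#' bilinear decoder, the `d x d` score matrix.
#'
#' @param enc_config An [encoder_config()].
#' @param F Input feature dimension.
#' @param n_classes Number of classes `c`.
#' @param seed Integer seed.
#' @param decoder `"bilinear"` or `"inner"`.
#' @return `list(encoder, clf, dec)` ready for [fit()] / [encode()].
#' @export
init_params <- function(enc_config, F, n_classes, seed = 1L,
                        decoder = c("bilinear", "inner")) {
  decoder <- match.arg(decoder)
  set.seed(derive_seed(seed, 401L))
  ins <- layer_input_dims(enc_config, F)
  L <- length(enc_config$layer_dims)
  enc <- vector("list", L)
  for (l in seq_len(L)) {
    Fp <- enc_config$layer_dims[l]
    if (enc_config$kind == "gat") {
      K <- enc_config$heads[l]
      Ws <- lapply(seq_len(K), function(k) glorot_uniform(Fp, ins[l]))
      as <- lapply(seq_len(K), function(k)
        drop(glorot_uniform(2L * Fp, 1L, fan_in = 2L * Fp, fan_out = 1L)))
      enc[[l]] <- list(W = Ws, a = as)
    } else {
      enc[[l]] <- list(W = glorot_uniform(Fp, ins[l]))
    }
  }
  d <- embedding_dim(enc_config)
  clf <- list(W = glorot_uniform(d, n_classes, fan_in = d, fan_out = n_classes),
              b = numeric(n_classes))
  dec <- if (decoder == "bilinear")
    list(kind = "bilinear", M = glorot_uniform(d, d), b = 0)
  else list(kind = "inner")
  list(encoder = enc, clf = clf, dec = dec)
}

# ---- optimizers -------------------------------------------------------------

adam_init <- function(params) {
  list(t = 0L, m = zero_like(params), v = zero_like(params))
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  state$m <- map_leaves2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map_leaves2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  step <- map_leaves2(state$m, state$v, function(m, v)
    lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- map_leaves2(params, step, `-`)
  list(params = params, state = state)
}

sgd_update <- function(params, grads, state, lr) {
  list(params = map_leaves2(params, grads, function(p, g) p - lr * g),
       state = state)
}

# ---- batch preparation and stepping -----------------------------------------

#' Assemble the full-batch training inputs
#'
#' Precomputes the encoder's graph structures (edge lists with self-loops, or
#' the normalized adjacency) and the link-loss targets from the training
#' adjacency. Classification targets come from the node split's train mask;
#' link targets always come from `A_train`, i.e. the hidden evaluation edges
#' are never seen.
#'
#' @param g An [attributed_graph()].
#' @param node_split From [split_nodes()].
#' @param edge_split From [hide_edges()].
#' @param enc_config An [encoder_config()].
#' @param tr_config A [train_config()].
#' @return A batch list consumed by [train_step()].
#' @export
prepare_batch <- function(g, node_split, edge_split, enc_config, tr_config) {
  A_train <- edge_split$A_train
  prep <- prep_encoder_graph(A_train, enc_config)
  mode <- tr_config$lp_mode
  if (mode == "auto")
    mode <- if (g$n <= tr_config$lp_exact_max_n) "exact" else "sampled"
  lp <- if (mode == "exact") {
    Ad <- as.matrix(A_train)
    list(mode = "exact", A_dense = Ad, ut = which(upper.tri(Ad)))
  } else {
    list(mode = "sampled", pos = edge_list(A_train), Ad = as.matrix(A_train))
  }
  list(Z = g$Z, n = g$n, prep = prep, labels = g$labels,
       train_mask = node_split$train_mask, lp = lp)
}

#' One training step
#'
#' Full-batch forward pass (encoder, both heads, joint loss), backward pass,
#' and one optimizer update. Dropout and negative-sampling draws come from the
#' current RNG stream.
#'
#' @param state `list(params, opt)` as initialized by [fit()] (or `params`
#'   from [init_params()] plus `opt = NULL` for plain use).
#' @param batch From [prepare_batch()].
#' @param enc_config An [encoder_config()].
#' @param tr_config A [train_config()].
#' @return `list(state, loss)` where `loss` is the pre-update
#'   [total_loss()] record.
#' @export
train_step <- function(state, batch, enc_config, tr_config) {
  if (is.null(state$opt) && tr_config$optimizer == "adam")
    state$opt <- adam_init(state$params)
  fw <- model_forward(state$params, batch, enc_config, tr_config$alpha,
                      train_mode = TRUE)
  if (!is.finite(fw$loss$L)) {
    stop(sprintf(
      "non-finite training loss (L_NC = %g, L_LP = %g, alpha = %g); %s",
      fw$loss$L_NC, fw$loss$L_LP, fw$loss$alpha,
      "check learning rate and input scaling"), call. = FALSE)
  }
  grads <- model_backward(state$params, batch, enc_config, tr_config$alpha,
                          fw$cache)
  upd <- if (tr_config$optimizer == "adam")
    adam_update(state$params, grads, state$opt, tr_config$lr)
  else sgd_update(state$params, grads, state$opt, tr_config$lr)
  state$params <- upd$params
  state$opt <- upd$state
  list(state = state, loss = fw$loss)
}

#' Train the multi-task model
#'
#' Runs `epochs` full-batch steps of the joint objective
#' `L = L_NC + alpha * L_LP` on the training adjacency and labeled train
#' nodes. Deterministic given the seed and configuration; no early stopping.
#'
#' @param g An [attributed_graph()].
#' @param node_split From [split_nodes()].
#' @param edge_split From [hide_edges()].
#' @param enc_config An [encoder_config()].
#' @param tr_config A [train_config()].
#' @return An object of class `mtgnn_fit`: `list(params, history, enc_config,
#'   tr_config)` where `history` is a per-epoch data frame of `loss_nc`,
#'   `loss_lp`, `loss`, `val_acc`, `val_auc`.
#' @export
fit <- function(g, node_split, edge_split, enc_config, tr_config) {
  validate_attributed_graph(g)
  batch <- prepare_batch(g, node_split, edge_split, enc_config, tr_config)
  params <- init_params(enc_config, ncol(g$Z), g$n_classes,
                        seed = tr_config$seed, decoder = tr_config$decoder)
  state <- list(params = params,
                opt = if (tr_config$optimizer == "adam") adam_init(params) else NULL)
  epochs <- tr_config$epochs
  history <- data.frame(epoch = seq_len(epochs), loss_nc = NA_real_,
                        loss_lp = NA_real_, loss = NA_real_,
                        val_acc = NA_real_, val_auc = NA_real_)
  has_val_edges <- nrow(edge_split$pos_val) > 0L
  has_test_nodes <- any(node_split$test_mask)

  set.seed(derive_seed(tr_config$seed, 402L))
  for (ep in seq_len(epochs)) {
    st <- train_step(state, batch, enc_config, tr_config)
    state <- st$state
    history$loss_nc[ep] <- st$loss$L_NC
    history$loss_lp[ep] <- st$loss$L_LP
    history$loss[ep] <- st$loss$L

    if (tr_config$eval_every > 0L && ep %% tr_config$eval_every == 0L) {
      H <- encoder_forward(batch$Z, state$params$encoder, enc_config,
                           batch$prep, train_mode = FALSE)$H
      if (has_test_nodes) {
        P <- class_probabilities(H, state$params$clf)
        pred <- argmax_first(P) - 1L
        history$val_acc[ep] <- accuracy(pred, g$labels, node_split$test_mask)
      }
      if (has_val_edges) {
        sp <- pair_scores(H, state$params$dec, edge_split$pos_val)
        sn <- pair_scores(H, state$params$dec, edge_split$neg_val)
        history$val_auc[ep] <- roc_auc(sp, sn)
      }
    }
    if (tr_config$log_every > 0L && ep %% tr_config$log_every == 0L) {
      message(sprintf("epoch %4d  L = %.4f  (L_NC = %.4f, L_LP = %.4f)",
                      ep, st$loss$L, st$loss$L_NC, st$loss$L_LP))
    }
  }
  structure(list(params = state$params, history = history,
                 enc_config = enc_config, tr_config = tr_config),
            class = "mtgnn_fit")
}

#' @export
print.mtgnn_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("mtgnn_fit: %s encoder, %d epochs, alpha = %g, final L = %.4f\n",
              x$enc_config$kind, nrow(h), x$tr_config$alpha,
              h$loss[nrow(h)]))
  invisible(x)
}
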