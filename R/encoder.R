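# Shared graph encoder f mapping (A, Z) -> H.
#
# Two interchangeable layer families:
#  * gat: multi-head masked attention. Per head, features are linearly
#    transformed (W), pairwise logits e_ij = LeakyReLU(a . [Wh_i || Wh_j]) are
#    softmax-normalized over each node's neighborhood (self-loops included so
#    the softmax is always defined), and neighbor features are aggregated with
#    those weights. Hidden layers concatenate heads, the final layer averages.
#  * gcn: symmetric-normalized propagation H' = sigma(D^-1/2 (A+I) D^-1/2 H W).
#
# The hot path works on a directed edge list (both orientations plus
# self-loops) with grouped rowsum/softmax rather than dense n x n attention
# matrices; the test suite checks it against a dense reference.

#' Encoder configuration
#'
#' @param kind `"gat"` or `"gcn"`.
#' @param layer_dims Output width of each layer (per head for `gat`). The last
#'   entry is the embedding dimension `d`.
#' @param heads Attention heads per layer (`gat` only). Hidden layers
#'   concatenate their heads; the final layer averages them.
#' @param dropout Dropout rate applied (in training mode) to each layer's
#'   input features and, for `gat`, to the normalized attention coefficients.
#' @param leaky_slope Negative slope of the LeakyReLU inside the attention
#'   logits.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(kind = c("gat", "gcn"), layer_dims = c(8L, 64L),
                           heads = c(8L, 1L), dropout = 0.1,
                           leaky_slope = 0.2) {
  kind <- match.arg(kind)
  layer_dims <- as.integer(layer_dims)
  heads <- as.integer(heads)
  if (length(heads) == 1L) heads <- rep(heads, length(layer_dims))
  if (kind == "gat" && length(heads) != length(layer_dims))
    stop("heads must have one entry per layer", call. = FALSE)
  if (any(layer_dims < 1L)) stop("layer_dims must be positive", call. = FALSE)
  if (any(heads < 1L)) stop("heads must be >= 1", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)", call. = FALSE)
  structure(list(kind = kind, layer_dims = layer_dims, heads = heads,
                 dropout = dropout, leaky_slope = leaky_slope),
            class = "encoder_config")
}

# Input width of each layer given the raw feature dimension.
layer_input_dims <- function(config, F) {
  L <- length(config$layer_dims)
  ins <- integer(L)
  ins[1L] <- F
  if (L > 1L) for (l in 2L:L) {
    ins[l] <- if (config$kind == "gat")
      config$layer_dims[l - 1L] * config$heads[l - 1L]
    else config$layer_dims[l - 1L]
  }
  ins
}

#' Embedding dimension implied by an encoder configuration
#' @param config An [encoder_config()].
#' @return The width `d` of the final embeddings.
#' @export
embedding_dim <- function(config) {
  config$layer_dims[length(config$layer_dims)]
}

#' Raw attention logit between two transformed node features
#'
#' `e_ij = LeakyReLU(a . [Wh_i || Wh_j])`: the unnormalized attention a node
#' `i` pays to neighbor `j`, computed from the already-transformed features.
#'
#' @param Wh_i,Wh_j Transformed feature vectors of equal width.
#' @param a Attention vector of length `2 * length(Wh_i)`.
#' @param leaky_slope Negative slope of the LeakyReLU.
#' @return Scalar logit.
#' @export
attention_logits <- function(Wh_i, Wh_j, a, leaky_slope = 0.2) {
  if (length(Wh_i) != length(Wh_j))
    stop("transformed features must have equal width", call. = FALSE)
  if (length(a) != 2L * length(Wh_i))
    stop("attention vector must have length 2 * F'", call. = FALSE)
  leaky_relu(sum(a * c(Wh_i, Wh_j)), leaky_slope)
}

#' Softmax-normalize attention logits over a neighborhood
#'
#' @param logits Numeric vector of logits over a node's (nonempty)
#'   neighborhood.
#' @return Coefficients summing to one; computed with max-subtraction.
#' @export
normalize_attention <- function(logits) {
  if (!length(logits)) stop("neighborhood is empty", call. = FALSE)
  e <- exp(logits - max(logits))
  e / sum(e)
}

# ---- internal edge-list machinery -----------------------------------------

# Directed edge list with self-loops from a symmetric adjacency, plus the
# per-target-node grouping reused across heads/epochs.
prep_gat_graph <- function(A) {
  n <- nrow(A)
  T <- methods::as(methods::as(A, "generalMatrix"), "TsparseMatrix")
  ei <- c(T@i + 1L, seq_len(n))
  ej <- c(T@j + 1L, seq_len(n))
  list(n = n, ei = ei, ej = ej,
       groups = split(seq_along(ei), factor(ei, levels = seq_len(n))))
}

# Grouped max over the edge list (for stable softmax).
group_max <- function(x, groups) {
  vapply(groups, function(ix) max(x[ix]), numeric(1), USE.NAMES = FALSE)
}

# One attention head, forward. Returns aggregation pre-activation plus the
# intermediates needed for the backward pass.
gat_head_forward <- function(H, W, a, slope, gp, attn_keep = NULL, dropout = 0) {
  Fp <- nrow(W)
  HW <- H %*% t(W)
  a1 <- a[seq_len(Fp)]; a2 <- a[Fp + seq_len(Fp)]
  s <- drop(HW %*% a1); d <- drop(HW %*% a2)
  pre_e <- s[gp$ei] + d[gp$ej]
  e <- leaky_relu(pre_e, slope)
  m <- group_max(e, gp$groups)
  ex <- exp(e - m[gp$ei])
  denom <- rowsum(ex, gp$ei)[, 1L]
  alpha <- ex / denom[gp$ei]
  alpha_used <- if (!is.null(attn_keep)) alpha * attn_keep / (1 - dropout) else alpha
  out_pre <- rowsum(alpha_used * HW[gp$ej, , drop = FALSE], gp$ei)
  list(HW = HW, pre_e = pre_e, alpha = alpha, alpha_used = alpha_used,
       attn_keep = attn_keep, out_pre = out_pre)
}

# Full GAT layer forward with cache. layer_params: list(W = list, a = list).
gat_layer_forward <- function(H_in, layer_params, gp, slope, merge, activation,
                              dropout = 0, train_mode = FALSE) {
  K <- length(layer_params$W)
  in_keep <- NULL
  H_use <- H_in
  if (train_mode && dropout > 0) {
    in_keep <- matrix(rbinom(length(H_in), 1L, 1 - dropout), nrow(H_in), ncol(H_in))
    H_use <- H_in * in_keep / (1 - dropout)
  }
  heads <- vector("list", K)
  acts <- vector("list", K)
  for (k in seq_len(K)) {
    attn_keep <- NULL
    if (train_mode && dropout > 0) {
      nE <- length(gp$ei)
      attn_keep <- rbinom(nE, 1L, 1 - dropout)
    }
    hf <- gat_head_forward(H_use, layer_params$W[[k]], layer_params$a[[k]],
                           slope, gp, attn_keep, dropout)
    heads[[k]] <- hf
    acts[[k]] <- if (activation == "elu") elu(hf$out_pre) else hf$out_pre
  }
  out <- if (merge == "concat") do.call(cbind, acts)
         else Reduce(`+`, acts) / K
  list(out = out, cache = list(H_in = H_in, H_use = H_use, in_keep = in_keep,
                               heads = heads, acts = acts, merge = merge,
                               activation = activation, dropout = dropout,
                               train_mode = train_mode))
}

# ---- public layer ops ------------------------------------------------------

#' Apply one graph attention layer
#'
#' Reference-style entry point operating on an explicit adjacency *with
#' self-loops*. `W` and `a` may be single parameter arrays (one head) or lists
#' of per-head arrays.
#'
#' @param H_in `n x F` input features.
#' @param A_loop Adjacency including self-loops (any matrix class).
#' @param W Per-head `F' x F` weight matrix or list thereof.
#' @param a Per-head attention vector of length `2F'` or list thereof.
#' @param leaky_slope LeakyReLU slope for the logits.
#' @param activation `"elu"` or `"identity"`, applied per head before merging.
#' @param merge `"concat"` or `"mean"` across heads.
#' @param dropout Dropout rate used when `train_mode = TRUE`.
#' @param train_mode Apply dropout to input features and attention
#'   coefficients (draws from the current RNG stream).
#' @return `n x F'K` (concat) or `n x F'` (mean) output features.
#' @export
gat_layer <- function(H_in, A_loop, W, a, leaky_slope = 0.2,
                      activation = c("elu", "identity"),
                      merge = c("concat", "mean"), dropout = 0,
                      train_mode = FALSE) {
  activation <- match.arg(activation)
  merge <- match.arg(merge)
  if (!is.list(W)) W <- list(W)
  if (!is.list(a)) a <- list(a)
  H_in <- as.matrix(H_in)
  for (k in seq_along(W)) {
    if (ncol(W[[k]]) != ncol(H_in)) stop("W width must match input features", call. = FALSE)
    if (length(a[[k]]) != 2L * nrow(W[[k]])) stop("attention vector has wrong length", call. = FALSE)
  }
  A_loop <- Matrix::Matrix(A_loop, sparse = TRUE)
  if (any(Matrix::diag(A_loop) == 0))
    stop("A_loop must include self-loops", call. = FALSE)
  n <- nrow(A_loop)
  T <- methods::as(methods::as(A_loop, "generalMatrix"), "TsparseMatrix")
  gp <- list(n = n, ei = T@i + 1L, ej = T@j + 1L,
             groups = split(seq_along(T@i), factor(T@i + 1L, levels = seq_len(n))))
  gat_layer_forward(H_in, list(W = W, a = a), gp, leaky_slope, merge,
                    activation, dropout, train_mode)$out
}

#' Symmetric-normalized adjacency with self-loops
#'
#' `D^-1/2 (A + I) D^-1/2` where `D` is the degree matrix of `A + I`; the
#' propagation operator of the convolutional encoder.
#'
#' @param A Symmetric adjacency without self-loops.
#' @return Dense normalized matrix.
#' @export
normalized_adjacency <- function(A) {
  AI <- as.matrix(A) + diag(nrow(A))
  dis <- 1 / sqrt(rowSums(AI))
  AI * outer(dis, dis)
}

#' Apply one graph convolution layer
#'
#' `H_out = sigma(A_hat H_in W^T)` with `A_hat` the pre-computed
#' symmetric-normalized adjacency (see [normalized_adjacency()]).
#'
#' @param H_in `n x F` input features.
#' @param A_hat Normalized adjacency.
#' @param W `F' x F` weight matrix.
#' @param activation `"elu"` or `"identity"`.
#' @return `n x F'` output features.
#' @export
gcn_layer <- function(H_in, A_hat, W, activation = c("elu", "identity")) {
  activation <- match.arg(activation)
  H_in <- as.matrix(H_in)
  if (ncol(W) != ncol(H_in)) stop("W width must match input features", call. = FALSE)
  pre <- as.matrix(A_hat %*% H_in) %*% t(W)
  if (activation == "elu") elu(pre) else pre
}

gcn_layer_forward <- function(H_in, W, A_hat, activation, dropout = 0,
                              train_mode = FALSE) {
  in_keep <- NULL
  H_use <- H_in
  if (train_mode && dropout > 0) {
    in_keep <- matrix(rbinom(length(H_in), 1L, 1 - dropout), nrow(H_in), ncol(H_in))
    H_use <- H_in * in_keep / (1 - dropout)
  }
  X <- as.matrix(A_hat %*% H_use)
  pre <- X %*% t(W)
  out <- if (activation == "elu") elu(pre) else pre
  list(out = out, cache = list(H_in = H_in, H_use = H_use, in_keep = in_keep,
                               X = X, pre = pre, activation = activation,
                               dropout = dropout))
}

# Precompute everything the encoder needs from a training adjacency.
prep_encoder_graph <- function(A_train, config) {
  if (config$kind == "gat") list(gp = prep_gat_graph(A_train))
  else list(A_hat = normalized_adjacency(A_train))
}

# Layer conventions: ELU + concat on hidden layers, identity + mean on the
# final layer.
layer_activation <- function(l, L) if (l < L) "elu" else "identity"
layer_merge <- function(l, L) if (l < L) "concat" else "mean"

# Stacked encoder forward with caches (shared by encode() and the trainer).
encoder_forward <- function(Z, params, config, prep, train_mode = FALSE) {
  L <- length(config$layer_dims)
  H <- Z
  caches <- vector("list", L)
  for (l in seq_len(L)) {
    if (config$kind == "gat") {
      fw <- gat_layer_forward(H, params[[l]], prep$gp, config$leaky_slope,
                              layer_merge(l, L), layer_activation(l, L),
                              config$dropout, train_mode)
    } else {
      fw <- gcn_layer_forward(H, params[[l]]$W, prep$A_hat,
                              layer_activation(l, L), config$dropout,
                              train_mode)
    }
    caches[[l]] <- fw$cache
    H <- fw$out
  }
  list(H = H, caches = caches)
}

#' Compute node embeddings
#'
#' Runs the stacked encoder on a (training) adjacency and feature matrix.
#' Self-loops are added internally for attention; the convolutional variant
#' uses the symmetric-normalized adjacency. With `train_mode = FALSE` the
#' result is deterministic given the parameters.
#'
#' @param A Symmetric adjacency without self-loops (typically
#'   `edge_split$A_train`).
#' @param Z Node feature matrix.
#' @param config An [encoder_config()].
#' @param params Encoder parameters as produced by [init_params()]
#'   (`$encoder` component).
#' @param train_mode Enable dropout (draws from the current RNG stream).
#' @return `n x d` embedding matrix `H`.
#' @export
encode <- function(A, Z, config, params, train_mode = FALSE) {
  prep <- prep_encoder_graph(A, config)
  encoder_forward(as.matrix(Z), params, config, prep, train_mode)$H
}
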