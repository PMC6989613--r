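# Task heads and losses.
#
# Classification: P_v = softmax(W^T h_v + b), loss = mean over labeled nodes
# of -log P_{v, y_v} (cross-entropy / negative log likelihood).
# Link prediction: S_ij = sigmoid(h_i^T M_sym h_j + b) (bilinear; M is
# symmetrized so the score is order-invariant) or sigmoid(h_i . h_j) (inner),
# loss = mean binary cross-entropy against adjacency targets.
# Joint objective: L = L_NC + alpha * L_LP.
#
# Both losses are means rather than raw sums, making the learning rate
# independent of graph size; the constant factor is otherwise absorbable into
# the rate.

#' Classifier head
#'
#' @param W `d x c` weight matrix.
#' @param b Length-`c` bias.
#' @return A `classifier_head` list.
#' @export
classifier_head <- function(W, b = numeric(ncol(W))) {
  stopifnot(is.matrix(W), length(b) == ncol(W), all(is.finite(W)), all(is.finite(b)))
  structure(list(W = W, b = as.numeric(b)), class = "classifier_head")
}

#' Link decoder
#'
#' @param kind `"bilinear"` (`sigmoid(h_i^T ((M + M^T)/2) h_j + b)`, with its
#'   own trainable parameters) or `"inner"` (`sigmoid(h_i . h_j)`, parameter
#'   free).
#' @param M `d x d` matrix (bilinear only).
#' @param b Scalar bias (bilinear only).
#' @return A `link_decoder` list.
#' @export
link_decoder <- function(kind = c("bilinear", "inner"), M = NULL, b = 0) {
  kind <- match.arg(kind)
  if (kind == "bilinear") {
    stopifnot(is.matrix(M), nrow(M) == ncol(M), all(is.finite(M)), is.finite(b))
    structure(list(kind = kind, M = M, b = as.numeric(b)), class = "link_decoder")
  } else {
    structure(list(kind = kind), class = "link_decoder")
  }
}

#' Class probabilities from embeddings
#'
#' @param H `n x d` embedding matrix.
#' @param head A [classifier_head()].
#' @return `n x c` matrix of row-stochastic class probabilities.
#' @export
class_probabilities <- function(H, head) {
  if (ncol(H) != nrow(head$W)) stop("embedding width does not match the head", call. = FALSE)
  logits <- sweep(H %*% head$W, 2L, head$b, `+`)
  softmax_rows(logits)
}

#' Node-classification loss
#'
#' Mean over masked (labeled) nodes of the negative log probability assigned
#' to the true class; logs clipped at `1e-12`.
#'
#' @param P `n x c` probability matrix.
#' @param labels 0-based integer labels (may contain `NA` outside the mask).
#' @param mask Logical vector selecting the labeled nodes to average over.
#' @return Non-negative scalar.
#' @export
nc_loss <- function(P, labels, mask) {
  idx <- which(mask)
  if (!length(idx)) stop("mask selects no nodes", call. = FALSE)
  p <- P[cbind(idx, labels[idx] + 1L)]
  mean(-log(pmax(p, LOG_EPS)))
}

#' Link score for a node pair
#'
#' @param h_i,h_j Embedding vectors of equal width.
#' @param decoder A [link_decoder()].
#' @return Probability `S_ij` in (0, 1); symmetric in `(i, j)`.
#' @export
link_score <- function(h_i, h_j, decoder) {
  if (length(h_i) != length(h_j)) stop("embeddings must have equal width", call. = FALSE)
  if (decoder$kind == "bilinear") {
    Ms <- (decoder$M + t(decoder$M)) / 2
    sigmoid(drop(h_i %*% Ms %*% h_j) + decoder$b)
  } else {
    sigmoid(sum(h_i * h_j))
  }
}

# Scores for a two-column pair index matrix (vectorized link_score).
pair_scores <- function(H, decoder, pairs) {
  if (!nrow(pairs)) return(numeric(0))
  if (decoder$kind == "bilinear") {
    Ms <- (decoder$M + t(decoder$M)) / 2
    q <- rowSums((H[pairs[, 1L], , drop = FALSE] %*% Ms) *
                 H[pairs[, 2L], , drop = FALSE]) + decoder$b
  } else {
    q <- rowSums(H[pairs[, 1L], , drop = FALSE] * H[pairs[, 2L], , drop = FALSE])
  }
  sigmoid(q)
}

#' Link-prediction loss over explicit pair sets
#'
#' Mean binary cross-entropy over the union of positive (target 1) and
#' negative (target 0) pairs; logs clipped at `1e-12`. During training on
#' small graphs the trainer instead evaluates the loss over *all* unordered
#' non-self pairs with targets from the training adjacency (see
#' [train_config()]`$lp_mode`); this function is that loss restricted to a
#' given pair sample.
#'
#' @param H Embedding matrix.
#' @param decoder A [link_decoder()].
#' @param pos_pairs,neg_pairs Two-column index matrices; together nonempty.
#' @return Non-negative scalar.
#' @export
lp_loss <- function(H, decoder, pos_pairs, neg_pairs) {
  np <- nrow(pos_pairs); nn <- nrow(neg_pairs)
  if (np + nn == 0L) stop("no pairs supplied", call. = FALSE)
  s_pos <- pair_scores(H, decoder, pos_pairs)
  s_neg <- pair_scores(H, decoder, neg_pairs)
  tot <- -sum(log(pmax(s_pos, LOG_EPS))) - sum(log(pmax(1 - s_neg, LOG_EPS)))
  tot / (np + nn)
}

# Dense all-pairs link loss against a training adjacency (exact mode).
# ut_mask / targets are precomputed by the trainer.
lp_loss_dense <- function(H, decoder, A_dense, ut) {
  Q <- lp_logits_dense(H, decoder)
  S <- sigmoid(Q[ut])
  t <- A_dense[ut]
  mean(-(t * log(pmax(S, LOG_EPS)) + (1 - t) * log(pmax(1 - S, LOG_EPS))))
}

lp_logits_dense <- function(H, decoder) {
  if (decoder$kind == "bilinear") {
    Ms <- (decoder$M + t(decoder$M)) / 2
    (H %*% Ms) %*% t(H) + decoder$b
  } else {
    H %*% t(H)
  }
}

#' Combine task losses
#'
#' @param L_NC Classification loss.
#' @param L_LP Link-prediction loss.
#' @param alpha Non-negative tradeoff weight.
#' @return A `loss_values` list with `L_NC`, `L_LP`, `alpha` and the total
#'   `L = L_NC + alpha * L_LP`.
#' @export
total_loss <- function(L_NC, L_LP, alpha) {
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  structure(list(L_NC = L_NC, L_LP = L_LP, alpha = alpha,
                 L = L_NC + alpha * L_LP),
            class = "loss_values")
}
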