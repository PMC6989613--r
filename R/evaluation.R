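# Metrics and experiment drivers.
#
# AUC uses the tie-aware Mann-Whitney estimator (exact, no threshold grid);
# average precision is precision averaged at the rank of each positive, with
# ties resolved by stable original order so results are deterministic.

#' Classification accuracy over a node mask
#'
#' @param pred_labels Predicted 0-based integer labels (length n).
#' @param true_labels True labels (may contain `NA` outside the mask).
#' @param mask Logical vector selecting the nodes to score.
#' @return Fraction correct in `[0, 1]`.
#' @export
accuracy <- function(pred_labels, true_labels, mask) {
  idx <- which(mask)
  if (!length(idx)) stop("mask selects no nodes", call. = FALSE)
  mean(pred_labels[idx] == true_labels[idx])
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `(concordant + 0.5 * ties) / (n_pos * n_neg)`: the probability that a
#' random positive outscores a random negative, with ties counted half.
#'
#' @param pos_scores Scores of true (positive) instances.
#' @param neg_scores Scores of negative instances.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0L || nn == 0L) stop("both score sets must be nonempty", call. = FALSE)
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Average precision of a ranked list
#'
#' Instances are sorted by descending score (ties keep their original order);
#' AP is the mean of precision evaluated at the rank of each positive.
#'
#' @param scores Numeric scores.
#' @param targets Binary vector (1 = positive) of the same length; at least
#'   one positive.
#' @return AP in `(0, 1]`.
#' @export
average_precision <- function(scores, targets) {
  if (length(scores) != length(targets)) stop("lengths differ", call. = FALSE)
  if (!any(targets == 1)) stop("no positive targets", call. = FALSE)
  ord <- order(-scores)  # radix sort: stable for ties
  t_sorted <- targets[ord]
  prec <- cumsum(t_sorted) / seq_along(t_sorted)
  mean(prec[t_sorted == 1])
}

#' Evaluate a trained model on held-out nodes and edges
#'
#' Embeds on the training adjacency with dropout off, then scores test-mask
#' node accuracy and held-out-edge AUC/AP (hidden positives vs sampled
#' negatives).
#'
#' @param params Trained parameters (`$params` of an `mtgnn_fit`, or the
#'   fit object itself).
#' @param g The [attributed_graph()].
#' @param node_split From [split_nodes()].
#' @param edge_split From [hide_edges()].
#' @param enc_config The [encoder_config()] used in training (taken from the
#'   fit object when one is passed).
#' @return A `metrics_report` list: `accuracy`, `auc`, `ap`, `n_eval`.
#' @export
evaluate_model <- function(params, g, node_split, edge_split,
                           enc_config = NULL) {
  if (inherits(params, "mtgnn_fit")) {
    enc_config <- params$enc_config
    params <- params$params
  }
  if (is.null(enc_config)) stop("enc_config is required", call. = FALSE)
  H <- encode(edge_split$A_train, g$Z, enc_config, params$encoder,
              train_mode = FALSE)
  P <- class_probabilities(H, params$clf)
  pred <- argmax_first(P) - 1L
  acc <- accuracy(pred, g$labels, node_split$test_mask)
  sp <- pair_scores(H, params$dec, edge_split$pos_test)
  sn <- pair_scores(H, params$dec, edge_split$neg_test)
  auc <- roc_auc(sp, sn)
  ap <- average_precision(c(sp, sn), c(rep(1L, length(sp)), rep(0L, length(sn))))
  structure(list(accuracy = acc, auc = auc, ap = ap,
                 n_eval = list(nodes = sum(node_split$test_mask),
                               pos = length(sp), neg = length(sn))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy = %.4f (n = %d)   link AUC = %.4f   AP = %.4f (pos = %d, neg = %d)\n",
              x$accuracy, x$n_eval$nodes, x$auc, x$ap, x$n_eval$pos, x$n_eval$neg))
  invisible(x)
}

run_one <- function(g, enc_config, tr_config, train_ratio, val_frac, test_frac,
                    split_seed, train_seed, alpha = tr_config$alpha) {
  ns <- split_nodes(g, train_ratio, seed = split_seed)
  es <- hide_edges(g, val_frac, test_frac, seed = split_seed)
  tc <- tr_config
  tc$alpha <- alpha
  tc$seed <- train_seed
  fitted <- fit(g, ns, es, enc_config, tc)
  evaluate_model(fitted, g, ns, es)
}

#' Sensitivity sweep over the loss tradeoff weight
#'
#' For each `alpha`, trains `repeats` models with distinct derived seeds
#' (splits are re-drawn per repeat and shared across alphas, so comparisons
#' are paired) and reports mean and sd of test accuracy, link AUC and AP.
#'
#' @param g An [attributed_graph()].
#' @param enc_config An [encoder_config()].
#' @param tr_config A [train_config()]; its `seed` is the sweep master seed.
#' @param alphas Tradeoff weights to evaluate (default 0 to 1 in steps
#'   of 0.1).
#' @param repeats Runs per alpha (default 10).
#' @param train_ratio,val_frac,test_frac Split fractions.
#' @return Data frame with one row per alpha (`mean_*`, `sd_*`, `repeats`);
#'   the per-run results are attached as attribute `"runs"`.
#' @export
alpha_sweep <- function(g, enc_config, tr_config,
                        alphas = seq(0, 1, by = 0.1), repeats = 10L,
                        train_ratio = 0.6, val_frac = 0.05, test_frac = 0.10) {
  stopifnot(repeats >= 1L)
  master <- tr_config$seed
  runs <- list()
  for (r in seq_len(repeats)) {
    split_seed <- derive_seed(master, 500L + r)
    for (ai in seq_along(alphas)) {
      train_seed <- derive_seed(master, 700L + 100L * r + ai)
      rep_res <- run_one(g, enc_config, tr_config, train_ratio, val_frac,
                         test_frac, split_seed, train_seed,
                         alpha = alphas[ai])
      runs[[length(runs) + 1L]] <- data.frame(
        alpha = alphas[ai], rep = r, accuracy = rep_res$accuracy,
        auc = rep_res$auc, ap = rep_res$ap)
    }
  }
  runs <- do.call(rbind, runs)
  agg <- do.call(rbind, lapply(split(runs, runs$alpha), function(df) {
    data.frame(alpha = df$alpha[1L],
               mean_accuracy = mean(df$accuracy), sd_accuracy = sd_or_zero(df$accuracy),
               mean_auc = mean(df$auc), sd_auc = sd_or_zero(df$auc),
               mean_ap = mean(df$ap), sd_ap = sd_or_zero(df$ap),
               repeats = nrow(df))
  }))
  agg <- agg[order(agg$alpha), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "runs") <- runs
  agg
}

#' Sensitivity sweep over the labeled-node training ratio
#'
#' Mirrors the standard label-ratio protocol: the train fraction of labeled
#' nodes varies over `ratios` (default 10 to 90 percent in steps of 10), with
#' `repeats` re-splits and re-trainings per ratio.
#'
#' @inheritParams alpha_sweep
#' @param ratios Train ratios to evaluate.
#' @return Data frame with one row per ratio; per-run results in attribute
#'   `"runs"`.
#' @export
ratio_sweep <- function(g, enc_config, tr_config,
                        ratios = seq(0.1, 0.9, by = 0.1), repeats = 10L,
                        val_frac = 0.05, test_frac = 0.10) {
  stopifnot(repeats >= 1L)
  master <- tr_config$seed
  runs <- list()
  for (r in seq_len(repeats)) {
    for (ri in seq_along(ratios)) {
      split_seed <- derive_seed(master, 1500L + 100L * r + ri)
      train_seed <- derive_seed(master, 2500L + 100L * r + ri)
      rep_res <- run_one(g, enc_config, tr_config, ratios[ri], val_frac,
                         test_frac, split_seed, train_seed)
      runs[[length(runs) + 1L]] <- data.frame(
        train_ratio = ratios[ri], rep = r, accuracy = rep_res$accuracy,
        auc = rep_res$auc, ap = rep_res$ap)
    }
  }
  runs <- do.call(rbind, runs)
  agg <- do.call(rbind, lapply(split(runs, runs$train_ratio), function(df) {
    data.frame(train_ratio = df$train_ratio[1L],
               mean_accuracy = mean(df$accuracy), sd_accuracy = sd_or_zero(df$accuracy),
               mean_auc = mean(df$auc), sd_auc = sd_or_zero(df$auc),
               mean_ap = mean(df$ap), sd_ap = sd_or_zero(df$ap),
               repeats = nrow(df))
  }))
  agg <- agg[order(agg$train_ratio), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "runs") <- runs
  agg
}

sd_or_zero <- function(x) if (length(x) > 1L) sd(x) else 0
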