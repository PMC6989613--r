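# Transductive evaluation splits: stratified labeled-node splits for the
# classification task, and edge hiding with matched negative sampling for the
# link prediction task. All splits are deterministic given their seed.

#' Stratified train/test split of labeled nodes
#'
#' Every labeled node is assigned to exactly one of the two masks. Per-class
#' train counts follow largest-remainder rounding of `train_ratio * n_k`
#' against a total of `round(train_ratio * n_labeled)`, so the realized split
#' is stratified up to rounding.
#'
#' @param g An [attributed_graph()] with at least one labeled node per class.
#' @param train_ratio Fraction of labeled nodes used for training, in (0, 1).
#' @param seed Integer seed.
#' @return A `node_split` list: logical `train_mask`, `test_mask` (length n),
#'   `train_ratio`, `seed`.
#' @export
split_nodes <- function(g, train_ratio, seed = 1L) {
  validate_attributed_graph(g)
  if (!(train_ratio > 0 && train_ratio < 1))
    stop("train_ratio must be in (0, 1)", call. = FALSE)
  labels <- g$labels
  labeled <- which(!is.na(labels))
  counts <- tabulate(labels[labeled] + 1L, nbins = g$n_classes)
  if (any(counts == 0L))
    stop("every class must have at least one labeled node", call. = FALSE)

  quota <- train_ratio * counts
  take <- floor(quota)
  total <- round(train_ratio * length(labeled))
  rem <- total - sum(take)
  if (rem > 0) {
    frac <- quota - take
    ord <- order(frac, seq_along(frac), decreasing = c(TRUE, FALSE), method = "radix")
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    frac <- quota - take
    ord <- order(frac, -seq_along(frac), method = "radix")
    k <- -rem
    cand <- ord[take[ord] > 0][seq_len(k)]
    take[cand] <- take[cand] - 1L
  }
  if (sum(take) < 1L || sum(take) >= length(labeled))
    stop("train_ratio leaves an empty train or test set", call. = FALSE)

  set.seed(derive_seed(seed, 301L))
  train_mask <- logical(g$n)
  for (k in seq_len(g$n_classes)) {
    members <- which(!is.na(labels) & labels == (k - 1L))
    chosen <- if (take[k] > 0) sample(members, take[k]) else integer(0)
    train_mask[chosen] <- TRUE
  }
  test_mask <- logical(g$n)
  test_mask[labeled] <- !train_mask[labeled]
  structure(list(train_mask = train_mask, test_mask = test_mask,
                 train_ratio = train_ratio, seed = as.integer(seed)),
            class = "node_split")
}

#' Hide edges for link-prediction evaluation
#'
#' Removes `floor(test_frac * m)` and `floor(val_frac * m)` uniformly chosen
#' edges from the adjacency (kept as held-out positives) and samples an equal
#' number of uniform non-edge pairs of the *original* graph as negatives.
#' The remaining edges form the training adjacency the encoder sees.
#'
#' @param g An [attributed_graph()] with at least 5 edges.
#' @param val_frac,test_frac Fractions of edges to hide (`val_frac +
#'   test_frac < 1`). Defaults 0.05 / 0.10.
#' @param seed Integer seed.
#' @return An `edge_split` list: `A_train` (symmetric `dgCMatrix`), two-column
#'   index matrices `pos_val`, `pos_test`, `neg_val`, `neg_test`, `fractions`,
#'   `seed`.
#' @export
hide_edges <- function(g, val_frac = 0.05, test_frac = 0.10, seed = 1L) {
  validate_attributed_graph(g)
  if (val_frac < 0 || test_frac < 0 || val_frac + test_frac >= 1)
    stop("need val_frac, test_frac >= 0 and val_frac + test_frac < 1", call. = FALSE)
  E <- edge_list(g$A)
  m <- nrow(E)
  if (m < 5L) stop("graph has fewer than 5 edges; edge split is degenerate", call. = FALSE)
  n_test <- floor(test_frac * m)
  n_val <- floor(val_frac * m)

  set.seed(derive_seed(seed, 302L))
  perm <- sample.int(m)
  test_idx <- perm[seq_len(n_test)]
  val_idx <- perm[n_test + seq_len(n_val)]
  pos_test <- E[test_idx, , drop = FALSE]
  pos_val <- E[val_idx, , drop = FALSE]

  A_train <- g$A
  drop <- c(test_idx, val_idx)
  if (length(drop)) {
    D <- E[drop, , drop = FALSE]
    A_train[cbind(D[, 1L], D[, 2L])] <- 0
    A_train[cbind(D[, 2L], D[, 1L])] <- 0
    A_train <- Matrix::drop0(A_train)
  }

  neg <- sample_negative_pairs(g, n_val + n_test, seed = derive_seed(seed, 303L))
  neg_test <- neg[seq_len(n_test), , drop = FALSE]
  neg_val <- neg[n_test + seq_len(n_val), , drop = FALSE]

  structure(list(A_train = A_train, pos_val = pos_val, pos_test = pos_test,
                 neg_val = neg_val, neg_test = neg_test,
                 fractions = c(val = val_frac, test = test_frac),
                 seed = as.integer(seed)),
            class = "edge_split")
}

#' Sample uniform non-edge pairs
#'
#' Draws `k` distinct unordered node pairs that carry no edge in `g`, exclude
#' self-pairs, and avoid an optional exclusion set.
#'
#' @param g An [attributed_graph()].
#' @param k Number of pairs.
#' @param exclude Optional two-column index matrix of pairs to avoid.
#' @param seed Integer seed.
#' @return `k x 2` integer matrix with `i < j` per row.
#' @export
sample_negative_pairs <- function(g, k, exclude = NULL, seed = 1L) {
  validate_attributed_graph(g)
  n <- g$n
  k <- as.integer(k)
  if (k == 0L) return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j"))))
  Ad <- as.matrix(g$A) != 0
  avail <- upper.tri(Ad) & !Ad
  if (!is.null(exclude) && nrow(exclude)) {
    lo <- pmin(exclude[, 1L], exclude[, 2L])
    hi <- pmax(exclude[, 1L], exclude[, 2L])
    avail[cbind(lo, hi)] <- FALSE
  }
  pool <- which(avail)
  if (k > length(pool))
    stop("requested more negative pairs than available non-edges", call. = FALSE)
  set.seed(derive_seed(seed, 304L))
  pick <- if (length(pool) == 1L) pool else sample(pool, k)
  i <- ((pick - 1L) %% n) + 1L
  j <- ((pick - 1L) %/% n) + 1L
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Serialize node and edge splits to TSV files
#'
#' Writes the boolean node masks and the hidden-edge/negative-pair lists as
#' plain TSV plus a YAML sidecar recording fractions and seeds, enough to
#' reconstruct the exact evaluation protocol.
#'
#' @param node_split A `node_split` (or `NULL`).
#' @param edge_split An `edge_split` (or `NULL`).
#' @param g The graph the splits belong to (for external node ids).
#' @param out_dir Output directory.
#' @return Character vector of written paths.
#' @export
write_splits <- function(node_split = NULL, edge_split = NULL, g, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir, call. = FALSE)
  paths <- character(0)
  meta <- list()
  if (!is.null(node_split)) {
    p <- file.path(out_dir, "node_split.tsv")
    df <- data.frame(id = g$node_ids,
                     split = ifelse(node_split$train_mask, "train",
                                    ifelse(node_split$test_mask, "test", "unlabeled")))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    meta$node_split <- list(train_ratio = node_split$train_ratio,
                            seed = node_split$seed)
  }
  if (!is.null(edge_split)) {
    for (nm in c("pos_val", "pos_test", "neg_val", "neg_test")) {
      p <- file.path(out_dir, paste0(nm, ".tsv"))
      M <- edge_split[[nm]]
      df <- data.frame(source = g$node_ids[M[, 1L]], target = g$node_ids[M[, 2L]])
      write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
    meta$edge_split <- list(val_frac = unname(edge_split$fractions["val"]),
                            test_frac = unname(edge_split$fractions["test"]),
                            seed = edge_split$seed)
  }
  sidecar <- file.path(out_dir, "splits.yaml")
  yaml::write_yaml(meta, sidecar)
  c(paths, sidecar)
}
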