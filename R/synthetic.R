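# Stochastic-block-model generator for attributed graphs.
#
# Blocks double as node classes: community structure carries the link signal,
# class-displaced Gaussian features carry the attribute signal. The two
# samplers draw from sub-seeds derived from the master seed by fixed offsets,
# so structure and features can be varied independently.

#' Configuration for the attributed SBM generator
#'
#' @param n Number of nodes.
#' @param classes Number of blocks/classes `c` (>= 2); blocks are assigned
#'   round-robin so sizes differ by at most one.
#' @param p_in Within-block edge probability.
#' @param p_out Between-block edge probability (`p_out <= p_in`).
#' @param F Feature dimension.
#' @param mu Pairwise distance between class feature centroids (exact when
#'   `F >= classes`, approximate otherwise).
#' @param sigma_f Per-coordinate Gaussian feature noise standard deviation.
#' @param seed Master seed.
#' @param binarize Threshold features at the per-coordinate centroid midpoint,
#'   yielding 0/1 bag-of-words-style features.
#' @return An `sbm_config` list.
#' @export
sbm_config <- function(n = 400L, classes = 4L, p_in = 0.08, p_out = 0.01,
                       F = 16L, mu = 1.0, sigma_f = 1.0, seed = 1L,
                       binarize = FALSE) {
  cfg <- list(n = as.integer(n), classes = as.integer(classes),
              p_in = p_in, p_out = p_out, F = as.integer(F),
              mu = mu, sigma_f = sigma_f, seed = as.integer(seed),
              binarize = isTRUE(binarize))
  if (!(0 <= cfg$p_out && cfg$p_out <= cfg$p_in && cfg$p_in <= 1))
    stop("need 0 <= p_out <= p_in <= 1", call. = FALSE)
  if (cfg$n < cfg$classes || cfg$classes < 2L)
    stop("need n >= classes >= 2", call. = FALSE)
  if (cfg$sigma_f < 0 || cfg$mu < 0) stop("mu and sigma_f must be >= 0", call. = FALSE)
  if (cfg$F < 1L) stop("F must be >= 1", call. = FALSE)
  structure(cfg, class = "sbm_config")
}

#' Sample a stochastic-block-model adjacency
#'
#' Labels are assigned round-robin (`node v` gets block `(v - 1) mod c`); each
#' unordered node pair receives an edge independently with probability `p_in`
#' inside a block and `p_out` across blocks.
#'
#' @param config An [sbm_config()].
#' @return `list(A, labels)` with a symmetric binary `dgCMatrix` and 0-based
#'   integer block labels.
#' @export
sample_sbm_adjacency <- function(config) {
  stopifnot(inherits(config, "sbm_config"))
  n <- config$n
  labels <- as.integer((seq_len(n) - 1L) %% config$classes)
  set.seed(derive_seed(config$seed, 101L))
  ut <- which(upper.tri(matrix(0, n, n)))
  i <- ((ut - 1L) %% n) + 1L
  j <- ((ut - 1L) %/% n) + 1L
  p <- ifelse(labels[i] == labels[j], config$p_in, config$p_out)
  hit <- runif(length(ut)) < p
  A <- Matrix::sparseMatrix(i = c(i[hit], j[hit]), j = c(j[hit], i[hit]),
                            x = 1, dims = c(n, n))
  list(A = A, labels = labels)
}

# Class centroids on a sphere with pairwise distance mu: mutually orthogonal
# directions of norm mu/sqrt(2) (random unit vectors when F < classes, where
# the distance is only approximate).
class_centroids <- function(classes, F, mu) {
  G <- matrix(rnorm(classes * F), classes, F)
  if (F >= classes) {
    Q <- qr.Q(qr(t(G)))[, seq_len(classes), drop = FALSE]
    C <- t(Q)
  } else {
    C <- G / sqrt(rowSums(G^2))
  }
  C * (mu / sqrt(2))
}

#' Sample class-correlated node features
#'
#' Each node's feature row is its class centroid plus isotropic Gaussian
#' noise. Centroids are drawn once per call from the feature sub-seed.
#'
#' @param labels 0-based integer class labels (no `NA`).
#' @param F Feature dimension.
#' @param mu Pairwise centroid distance.
#' @param sigma_f Noise standard deviation.
#' @param seed Master seed (the feature sub-seed is derived internally).
#' @return `n x F` numeric matrix with the centroid matrix attached as
#'   attribute `"centroids"`.
#' @export
sample_class_features <- function(labels, F, mu, sigma_f, seed) {
  stopifnot(!anyNA(labels), all(labels >= 0L))
  classes <- max(labels) + 1L
  n <- length(labels)
  set.seed(derive_seed(seed, 202L))
  C <- class_centroids(classes, F, mu)
  Z <- C[labels + 1L, , drop = FALSE] +
    matrix(rnorm(n * F, sd = sigma_f), n, F)
  attr(Z, "centroids") <- C
  Z
}

#' Generate a complete attributed SBM dataset
#'
#' Composes [sample_sbm_adjacency()] and [sample_class_features()]; labels are
#' fully observed. With `binarize = TRUE` features are thresholded at the
#' per-coordinate mean of the class centroids.
#'
#' @param config An [sbm_config()].
#' @return An [attributed_graph()].
#' @export
make_synthetic_dataset <- function(config) {
  stopifnot(inherits(config, "sbm_config"))
  sb <- sample_sbm_adjacency(config)
  Z <- sample_class_features(sb$labels, config$F, config$mu, config$sigma_f,
                             config$seed)
  if (config$binarize) {
    mid <- colMeans(attr(Z, "centroids"))
    Z <- 1 * (sweep(Z, 2L, mid) > 0)
  }
  attr(Z, "centroids") <- NULL
  attributed_graph(sb$A, Z, sb$labels,
                   node_ids = sprintf("n%05d", seq_len(config$n)),
                   n_classes = config$classes)
}
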