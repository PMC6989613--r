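# Small shared numerics and seed plumbing.

LOG_EPS <- 1e-12

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic stages (graph structure, features, splits, parameter
#' initialization, dropout streams, repeat indices) draw their own sub-seed
#' from one master seed through this fixed congruential map, so that varying
#' one stage never perturbs another.
#'
#' @param seed Master seed (integer).
#' @param offset Integer tag identifying the consumer.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  x <- (abs(as.numeric(seed)) * 48271 + as.numeric(offset) * 104729 + 11) %% 2147483646
  as.integer(x) + 1L
}

sigmoid <- function(x) 1 / (1 + exp(-x))

elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(x))

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

# Row-wise numerically stable softmax of a dense matrix.
softmax_rows <- function(X) {
  m <- apply(X, 1L, max)
  E <- exp(X - m)
  E / rowSums(E)
}

# argmax with ties broken toward the lowest index (max.col would randomize).
argmax_first <- function(X) {
  n <- nrow(X)
  out <- rep.int(1L, n)
  best <- X[, 1L]
  for (k in seq_len(ncol(X))[-1L]) {
    better <- X[, k] > best
    out[better] <- k
    best[better] <- X[better, k]
  }
  out
}

glorot_uniform <- function(nrow, ncol, fan_in = ncol, fan_out = nrow) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# Element labels of a list whether or not it is named (parameter trees mix
# named lists with unnamed per-layer / per-head lists).
leaf_keys <- function(x) {
  nm <- names(x)
  if (is.null(nm)) as.character(seq_along(x))
  else ifelse(nzchar(nm), nm, as.character(seq_along(x)))
}

# Flatten a nested list of numeric arrays to one vector, and back; used by the
# optimizer state checks and the finite-difference gradient tests.
flatten_params <- function(p) {
  leaves <- list()
  walk <- function(x, path) {
    if (is.list(x)) {
      keys <- leaf_keys(x)
      for (i in seq_along(x)) walk(x[[i]], c(path, keys[i]))
    } else if (is.numeric(x)) {
      leaves[[paste(path, collapse = ".")]] <<- as.numeric(x)
    }
  }
  walk(p, character())
  unlist(leaves, use.names = TRUE)
}

unflatten_params <- function(vec, template) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) {
      for (i in seq_along(x)) x[[i]] <- walk(x[[i]])
      x
    } else if (is.numeric(x)) {
      k <- length(x)
      vals <- vec[(pos + 1L):(pos + k)]
      pos <<- pos + k
      if (is.matrix(x)) matrix(vals, nrow(x), ncol(x)) else as.numeric(vals)
    } else {
      x
    }
  }
  walk(template)
}

# Map over corresponding numeric leaves of two nested lists. Elements are
# matched by name when both sides are named (the companion tree may omit
# non-numeric fields), by position otherwise.
map_leaves2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    an <- names(a); bn <- names(b)
    for (i in seq_along(a)) {
      if (!is.numeric(a[[i]]) && !is.list(a[[i]])) next
      bi <- if (!is.null(an) && nzchar(an[i]) && !is.null(bn)) b[[an[i]]]
            else b[[i]]
      out[[i]] <- map_leaves2(a[[i]], bi, f)
    }
    out
  } else if (is.numeric(a)) {
    f(a, b)
  } else {
    a
  }
}

zero_like <- function(p) {
  if (is.list(p)) {
    out <- p
    for (i in seq_along(p)) out[[i]] <- zero_like(p[[i]])
    out
  } else if (is.numeric(p)) {
    p * 0
  } else {
    p
  }
}

max_abs_leaf <- function(p) {
  if (is.list(p)) {
    if (!length(p)) return(0)
    max(vapply(p, max_abs_leaf, numeric(1)))
  } else if (is.numeric(p)) {
    if (!length(p)) 0 else max(abs(p))
  } else {
    0
  }
}
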