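# Attributed graph container and tabular I/O.
#
# The container mirrors the usual transductive benchmark layout (citation
# graphs such as Cora/Citeseer/Pubmed): a symmetric unweighted adjacency A,
# a dense node-by-feature matrix Z, and an integer class label per node with
# NA marking unlabeled nodes. Class labels are 0-based, matching the on-disk
# convention of those benchmarks.

#' Construct and validate an attributed graph
#'
#' @param A Symmetric binary adjacency (`matrix` or any `Matrix` class); the
#'   diagonal must be zero.
#' @param Z Numeric node feature matrix with one row per node (`n x F`).
#' @param labels Integer class labels in `0..n_classes-1`, `NA` for unlabeled
#'   nodes. Defaults to all-`NA`.
#' @param node_ids Character vector of external node identifiers; defaults to
#'   `"v1" ... "vn"`.
#' @param n_classes Number of classes `c`. Defaults to `max(labels) + 1`
#'   (0 when no node is labeled).
#' @return An object of class `attributed_graph`: a list with elements `n`,
#'   `node_ids`, `A` (a `dgCMatrix`), `Z`, `labels`, `n_classes`.
#' @export
attributed_graph <- function(A, Z, labels = NULL, node_ids = NULL, n_classes = NULL) {
  Z <- as.matrix(Z)
  storage.mode(Z) <- "double"
  n <- nrow(Z)
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  A <- Matrix::drop0(A)
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  labels <- as.integer(labels)
  if (is.null(node_ids)) node_ids <- paste0("v", seq_len(n))
  node_ids <- as.character(node_ids)
  if (is.null(n_classes)) {
    n_classes <- if (all(is.na(labels))) 0L else max(labels, na.rm = TRUE) + 1L
  }
  g <- structure(
    list(n = n, node_ids = node_ids, A = A, Z = Z,
         labels = labels, n_classes = as.integer(n_classes)),
    class = "attributed_graph"
  )
  validate_attributed_graph(g)
  g
}

#' Check the structural invariants of an attributed graph
#'
#' Verifies that the adjacency is symmetric, binary and hollow (zero
#' diagonal), that features are finite with at least one column, and that
#' every non-missing label lies in `[0, n_classes)`.
#'
#' @param g An [attributed_graph()].
#' @return `g`, invisibly; signals an error on any violation.
#' @export
validate_attributed_graph <- function(g) {
  stopifnot(inherits(g, "attributed_graph"))
  A <- g$A
  if (nrow(A) != g$n || ncol(A) != g$n)
    stop("adjacency dimensions do not match the node count", call. = FALSE)
  if (!isTRUE(Matrix::isSymmetric(A, tol = 0)))
    stop("adjacency must be symmetric", call. = FALSE)
  x <- A@x
  if (length(x) && any(x != 1))
    stop("adjacency entries must be 0 or 1", call. = FALSE)
  if (any(Matrix::diag(A) != 0))
    stop("adjacency diagonal must be zero (no self-loops)", call. = FALSE)
  if (ncol(g$Z) < 1L) stop("feature matrix must have at least one column", call. = FALSE)
  if (nrow(g$Z) != g$n) stop("feature matrix must have one row per node", call. = FALSE)
  if (any(!is.finite(g$Z))) stop("feature matrix contains non-finite entries", call. = FALSE)
  if (length(g$labels) != g$n) stop("labels must have length n", call. = FALSE)
  lab <- g$labels[!is.na(g$labels)]
  if (length(lab) && (any(lab < 0L) || any(lab >= g$n_classes)))
    stop("labels must lie in [0, n_classes)", call. = FALSE)
  if (length(g$node_ids) != g$n || anyDuplicated(g$node_ids))
    stop("node_ids must be unique and of length n", call. = FALSE)
  invisible(g)
}

read_tsv_raw <- function(path, what = "table") {
  read.delim(path, header = FALSE, comment.char = "#",
             colClasses = "character", sep = "\t",
             stringsAsFactors = FALSE, blank.lines.skip = TRUE)
}

#' Load an attributed graph from tabular files
#'
#' Reads the three-file layout used throughout the package: an edge list
#' (two tab-separated columns of node ids; lines starting with `#` are
#' ignored), a node feature table (first column the node id, remaining columns
#' numeric; or a MatrixMarket `.mtx` file accompanied by `feature_ids_path`
#' with one id per line), and optionally a label table (id, integer class).
#'
#' Edges are undirected: duplicates and reversed orientations collapse to a
#' single edge, and self-loops are dropped with a warning. Node order (hence
#' internal indexing) is the row order of the feature table; nodes present
#' only there become isolated nodes.
#'
#' @param edge_path Path to the edge TSV.
#' @param feature_path Path to the feature TSV or `.mtx` file.
#' @param label_path Optional path to the label TSV.
#' @param feature_ids_path Required when `feature_path` is MatrixMarket: file
#'   with one node id per line, in matrix row order.
#' @param n_classes Optional declared class count; labels `>= n_classes` are a
#'   format error. Defaults to `max(label) + 1`.
#' @param row_normalize Divide each feature row by its L1 norm (rows of all
#'   zeros are left unchanged). Off by default.
#' @return An [attributed_graph()].
#' @export
load_dataset <- function(edge_path, feature_path, label_path = NULL,
                         feature_ids_path = NULL, n_classes = NULL,
                         row_normalize = FALSE) {
  if (grepl("\\.mtx$", feature_path)) {
    if (is.null(feature_ids_path))
      stop("feature_ids_path is required with a MatrixMarket feature file", call. = FALSE)
    Z <- as.matrix(Matrix::readMM(feature_path))
    ids <- readLines(feature_ids_path)
    ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
    if (length(ids) != nrow(Z))
      stop("feature id list length does not match the feature matrix", call. = FALSE)
  } else {
    tab <- read_tsv_raw(feature_path)
    if (ncol(tab) < 2L) stop("feature table needs an id column and >= 1 feature column", call. = FALSE)
    ids <- tab[[1L]]
    Z <- suppressWarnings(vapply(tab[-1L], as.numeric, numeric(nrow(tab))))
    Z <- matrix(as.numeric(Z), nrow = nrow(tab))
    if (any(is.na(Z)))
      stop("non-numeric feature cell in ", feature_path, call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate node ids in the feature table", call. = FALSE)
  n <- length(ids)

  etab <- tryCatch(read_tsv_raw(edge_path), error = function(e) NULL)
  if (is.null(etab) || nrow(etab) == 0L) {
    ei <- integer(0); ej <- integer(0)
  } else {
    if (ncol(etab) < 2L) stop("edge file must have two columns", call. = FALSE)
    ei <- match(etab[[1L]], ids)
    ej <- match(etab[[2L]], ids)
    if (any(is.na(ei)) || any(is.na(ej))) {
      bad <- unique(c(etab[[1L]][is.na(ei)], etab[[2L]][is.na(ej)]))
      stop("edge references node id(s) absent from the feature table: ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    loops <- ei == ej
    if (any(loops)) {
      warning(sum(loops), " self-loop(s) dropped from the edge list")
      ei <- ei[!loops]; ej <- ej[!loops]
    }
  }
  lo <- pmin(ei, ej); hi <- pmax(ei, ej)
  keep <- !duplicated(cbind(lo, hi))
  lo <- lo[keep]; hi <- hi[keep]
  A <- Matrix::sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = 1,
                            dims = c(n, n))

  labels <- rep(NA_integer_, n)
  if (!is.null(label_path)) {
    ltab <- read_tsv_raw(label_path)
    if (ncol(ltab) < 2L) stop("label file must have two columns (id, class)", call. = FALSE)
    li <- match(ltab[[1L]], ids)
    if (any(is.na(li)))
      stop("label references node id(s) absent from the feature table", call. = FALSE)
    lv <- suppressWarnings(as.integer(ltab[[2L]]))
    if (any(is.na(lv)) || any(lv < 0L))
      stop("labels must be non-negative integers", call. = FALSE)
    if (!is.null(n_classes) && any(lv >= n_classes))
      stop("label outside the declared number of classes", call. = FALSE)
    labels[li] <- lv
  }
  if (row_normalize) {
    s <- rowSums(abs(Z))
    nz <- s > 0
    Z[nz, ] <- Z[nz, , drop = FALSE] / s[nz]
  }
  attributed_graph(A, Z, labels, node_ids = ids, n_classes = n_classes)
}

#' Write an attributed graph to tabular files
#'
#' Emits `edges.tsv` (each undirected edge once, lexicographically smaller id
#' first), `features.tsv` (id plus full-precision feature columns) and
#' `labels.tsv` (id, class; labeled nodes only) under `out_dir`.
#' `load_dataset()` on the output reproduces the graph exactly.
#'
#' @param g An [attributed_graph()].
#' @param out_dir Output directory, created if needed.
#' @return Named character vector of the three file paths.
#' @export
write_dataset <- function(g, out_dir) {
  validate_attributed_graph(g)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir, call. = FALSE)
  paths <- c(edges = file.path(out_dir, "edges.tsv"),
             features = file.path(out_dir, "features.tsv"),
             labels = file.path(out_dir, "labels.tsv"))

  E <- edge_list(g$A)
  con <- file(paths[["edges"]], "w")
  writeLines("#source\ttarget", con)
  if (nrow(E)) {
    a <- g$node_ids[E[, 1L]]; b <- g$node_ids[E[, 2L]]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    writeLines(paste(a, b, sep = "\t"), con)
  }
  close(con)

  zfmt <- apply(g$Z, 2L, function(col) formatC(col, digits = 17, format = "g"))
  zfmt <- matrix(zfmt, nrow = g$n)
  con <- file(paths[["features"]], "w")
  writeLines(paste(c("#id", paste0("f", seq_len(ncol(g$Z)))), collapse = "\t"), con)
  writeLines(paste(g$node_ids, apply(zfmt, 1L, paste, collapse = "\t"), sep = "\t"), con)
  close(con)

  lab <- which(!is.na(g$labels))
  con <- file(paths[["labels"]], "w")
  writeLines("#id\tclass", con)
  if (length(lab))
    writeLines(paste(g$node_ids[lab], g$labels[lab], sep = "\t"), con)
  close(con)
  paths
}

# Upper-triangle edge list (i < j) of a symmetric sparse adjacency.
edge_list <- function(A) {
  T <- methods::as(methods::as(A, "generalMatrix"), "TsparseMatrix")
  i <- T@i + 1L; j <- T@j + 1L
  keep <- i < j
  cbind(i = i[keep], j = j[keep])
}

#' @export
print.attributed_graph <- function(x, ...) {
  m <- Matrix::nnzero(x$A) / 2
  cat(sprintf("attributed_graph: %d nodes, %d undirected edges, %d features, %d classes (%d labeled)\n",
              x$n, m, ncol(x$Z), x$n_classes, sum(!is.na(x$labels))))
  invisible(x)
}
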