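#' Weighted structural brain network
#'
#' A `weighted_network` wraps a symmetric nonnegative weight matrix with zero
#' diagonal, the universal currency of the analysis pipeline. `K` counts the
#' unordered node pairs with strictly positive weight.
#'
#' @param weights Symmetric nonnegative numeric matrix with zero diagonal.
#' @param node_labels Optional character vector of node identifiers; defaults
#'   to the matrix dimnames or `"n1"..."nN"`.
#' @return An object of class `weighted_network` with elements `weights`
#'   (labelled matrix), `node_labels`, `N` (node count) and `K` (edge count).
#' @export
weighted_network <- function(weights, node_labels = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("'weights' must be a numeric matrix")
  if (nrow(weights) != ncol(weights))
    stop("'weights' must be square")
  if (any(!is.finite(weights)))
    stop("'weights' must be finite")
  if (any(weights < 0))
    stop("'weights' must be nonnegative")
  if (any(abs(weights - t(weights)) > 1e-12))
    stop("'weights' must be symmetric")
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0))
    stop("'weights' must have a zero diagonal")
  n <- nrow(weights)
  if (is.null(node_labels)) {
    node_labels <- rownames(weights)
    if (is.null(node_labels)) node_labels <- paste0("n", seq_len(n))
  }
  if (length(node_labels) != n)
    stop("'node_labels' length must match the matrix dimension")
  dimnames(weights) <- list(node_labels, node_labels)
  structure(
    list(weights = weights, node_labels = node_labels, N = n,
         K = sum(weights[upper.tri(weights)] > 0)),
    class = "weighted_network"
  )
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("Weighted network: %d nodes, %d edges (sparsity %.4f)\n",
              x$N, x$K, sparsity(x)))
  w <- x$weights[upper.tri(x$weights)]
  w <- w[w > 0]
  if (length(w))
    cat(sprintf("  edge weights: min %.4g, mean %.4g, max %.4g\n",
                min(w), mean(w), max(w)))
  invisible(x)
}

# Accept either a weighted_network or a bare matrix everywhere downstream.
as_weight_matrix <- function(G) {
  if (inherits(G, "weighted_network")) return(G$weights)
  if (is.matrix(G)) return(weighted_network(G)$weights)
  stop("expected a 'weighted_network' or a weight matrix")
}

#' Build a subject's weighted network from connectivity tables
#'
#' Edge weight between regions i and j is `FN_ij * FA_ij / mean(vol_i, vol_j)`
#' wherever the fiber count reaches `fn_threshold`; all other pairs get zero.
#' The fiber-count floor suppresses spurious tractography connections.
#'
#' @param subject A `subject_connectivity` object (see [generate_cohort()]),
#'   or a list with elements `FN` (integer matrix), `FA` (matrix) and
#'   `volumes` (positive vector).
#' @param fn_threshold Minimum fiber count for a connection (default 10).
#' @return A [weighted_network()].
#' @export
build_network <- function(subject, fn_threshold = 10) {
  FN <- subject$FN
  FA <- subject$FA
  vol <- subject$volumes
  if (fn_threshold < 1) stop("'fn_threshold' must be >= 1")
  if (!is.matrix(FN) || !is.matrix(FA))
    stop("FN and FA must be matrices")
  if (!all(dim(FN) == dim(FA)) || length(vol) != nrow(FN))
    stop("dimension mismatch between FN, FA and volumes")
  if (any(vol <= 0)) stop("region volumes must be strictly positive")
  mean_vol <- outer(vol, vol, "+") / 2
  w <- ifelse(FN >= fn_threshold, FN * FA / mean_vol, 0)
  diag(w) <- 0
  labels <- if (!is.null(names(vol))) names(vol) else rownames(FN)
  weighted_network(w, node_labels = labels)
}

#' Normalize edge weights by the network's mean edge weight
#'
#' Divides every weight by the mean over the K existing (nonzero) edges, so
#' the mean nonzero weight of the result is exactly 1. This puts all subjects
#' at the same network cost before topological metrics are compared.
#'
#' @param G A [weighted_network()] or weight matrix with at least one edge.
#' @return A [weighted_network()] with unit mean edge weight.
#' @export
normalize_by_mean_weight <- function(G) {
  w <- as_weight_matrix(G)
  e <- w[upper.tri(w)]
  e <- e[e > 0]
  if (length(e) == 0)
    stop("cannot normalize an empty network (K = 0): unusable subject")
  weighted_network(w / mean(e))
}

#' Network sparsity
#'
#' Fraction of possible unordered node pairs that are connected,
#' `K / (N (N - 1) / 2)`.
#'
#' @param G A [weighted_network()] or weight matrix with at least two nodes.
#' @return A fraction in \[0, 1\].
#' @export
sparsity <- function(G) {
  G <- if (inherits(G, "weighted_network")) G else weighted_network(G)
  if (G$N < 2) stop("sparsity requires at least two nodes")
  G$K / (G$N * (G$N - 1) / 2)
}

#' Reduce a network to a target sparsity by removing the weakest edges
#'
#' Edges are deleted in increasing order of weight until the sparsity drops
#' to `target` or below; a network already at or below the target is
#' returned unchanged. Weight ties are broken by ascending (row, column)
#' index of the edge so the result is deterministic.
#'
#' @param G A [weighted_network()] or weight matrix.
#' @param target Target sparsity in \[0, 1\].
#' @return A [weighted_network()] with `sparsity(G) <= target`.
#' @export
match_sparsity <- function(G, target) {
  G <- if (inherits(G, "weighted_network")) G else weighted_network(G)
  if (target < 0 || target > 1) stop("'target' must be in [0, 1]")
  n_pairs <- G$N * (G$N - 1) / 2
  k_target <- floor(target * n_pairs + 1e-9)
  if (G$K <= k_target) return(G)
  w <- G$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  ord <- order(w[idx], idx[, 1], idx[, 2])
  drop <- idx[ord[seq_len(G$K - k_target)], , drop = FALSE]
  w[drop] <- 0
  w[drop[, c(2, 1), drop = FALSE]] <- 0
  weighted_network(w, node_labels = G$node_labels)
}

#' Read / write a network as a labelled dense CSV matrix
#'
#' @param G A [weighted_network()].
#' @param path CSV file path.
#' @return `write_network_csv` returns `path` invisibly; `read_network_csv`
#'   returns a [weighted_network()].
#' @export
write_network_csv <- function(G, path) {
  G <- if (inherits(G, "weighted_network")) G else weighted_network(G)
  utils::write.csv(as.data.frame(G$weights), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  weighted_network(as.matrix(df), node_labels = colnames(df))
}

#' Export a network as an edge-list TSV
#'
#' Three columns (`node_i`, `node_j`, `weight`), one row per existing edge,
#' upper-triangle order.
#'
#' @param G A [weighted_network()].
#' @param path TSV file path.
#' @return The edge-list data frame, invisibly if written to `path`.
#' @export
write_edge_list <- function(G, path = NULL) {
  G <- if (inherits(G, "weighted_network")) G else weighted_network(G)
  idx <- which(upper.tri(G$weights) & G$weights > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(node_i = G$node_labels[idx[, 1]],
                   node_j = G$node_labels[idx[, 2]],
                   weight = G$weights[idx])
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
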