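#' Exact one-tailed sign-test p-value for edge presence
#'
#' Under the null hypothesis that a connection does not exist, a subject
#' shows the edge with probability 1/2; the p-value is the exact upper
#' binomial tail `P(X >= k_present)` with `X ~ Binomial(n, 1/2)`, computed
#' from the exact binomial distribution (no normal approximation).
#'
#' @param k_present Number of subjects in which the edge exists.
#' @param n Number of subjects.
#' @return A probability in \[0, 1\] (vectorized over `k_present`).
#' @export
sign_test_pvalue <- function(k_present, n) {
  if (n < 1) stop("'n' must be at least 1")
  if (any(k_present < 0) || any(k_present > n))
    stop("'k_present' must lie in [0, n]")
  stats::pbinom(k_present - 1, n, 0.5, lower.tail = FALSE)
}

#' Group backbone network from per-subject networks
#'
#' For every region pair, counts the subjects possessing the edge and keeps
#' the edge when its sign-test p-value survives Bonferroni correction over
#' all `N(N-1)/2` possible edges at level `alpha`. A retained edge's weight
#' is the mean weight over only the subjects in which it exists. The
#' backbone captures the connections that are consistently present in a
#' group.
#'
#' @param networks A list of two or more [weighted_network()] objects (or
#'   weight matrices) with identical node sets and ordering.
#' @param alpha Significance level before Bonferroni correction
#'   (default 0.05).
#' @return A `backbone_network`: list with `network` (the retained
#'   [weighted_network()]), `presence_counts`, `pvalues`, `n_subjects`,
#'   `alpha` and `n_comparisons`.
#' @export
build_backbone <- function(networks, alpha = 0.05) {
  if (length(networks) < 2) stop("need at least two subject networks")
  mats <- lapply(networks, as_weight_matrix)
  n_nodes <- nrow(mats[[1]])
  labels <- rownames(mats[[1]])
  for (m in mats) {
    if (nrow(m) != n_nodes) stop("subject networks differ in dimension")
    if (!identical(rownames(m), labels))
      stop("subject networks differ in node ordering")
  }
  n <- length(mats)
  present <- Reduce(`+`, lapply(mats, function(m) (m > 0) * 1L))
  total <- Reduce(`+`, mats)
  pvals <- matrix(sign_test_pvalue(as.vector(present), n), n_nodes, n_nodes)
  diag(pvals) <- 1
  m_comp <- n_nodes * (n_nodes - 1) / 2
  keep <- pvals <= alpha / m_comp
  diag(keep) <- FALSE
  wmean <- matrix(0, n_nodes, n_nodes)
  nz <- keep & present > 0
  wmean[nz] <- total[nz] / present[nz]
  dimnames(wmean) <- dimnames(pvals) <- list(labels, labels)
  dimnames(present) <- list(labels, labels)
  structure(
    list(network = weighted_network(wmean, node_labels = labels),
         presence_counts = present, pvalues = pvals, n_subjects = n,
         alpha = alpha, n_comparisons = m_comp),
    class = "backbone_network"
  )
}

#' @export
print.backbone_network <- function(x, ...) {
  cat(sprintf(
    "Backbone network over %d subjects: %d of %d possible edges retained\n",
    x$n_subjects, x$network$K, x$n_comparisons))
  cat(sprintf("  sign test at alpha = %g, Bonferroni m = %d (p <= %.3g)\n",
              x$alpha, x$n_comparisons, x$alpha / x$n_comparisons))
  invisible(x)
}

#' Per-edge backbone report
#'
#' One row per possible region pair that exists in at least one subject:
#' presence count, sign-test p-value, retention flag and mean weight.
#'
#' @param backbone A `backbone_network` from [build_backbone()].
#' @param path Optional TSV output path.
#' @return The report data frame (invisibly when written to `path`).
#' @export
backbone_edge_report <- function(backbone, path = NULL) {
  stopifnot(inherits(backbone, "backbone_network"))
  cnt <- backbone$presence_counts
  idx <- which(upper.tri(cnt) & cnt > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  labels <- backbone$network$node_labels
  df <- data.frame(
    node_i = labels[idx[, 1]],
    node_j = labels[idx[, 2]],
    count = cnt[idx],
    p = backbone$pvalues[idx],
    retained = backbone$network$weights[idx] > 0,
    mean_weight = ifelse(backbone$network$weights[idx] > 0,
                         backbone$network$weights[idx], NA_real_)
  )
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
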