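#' Shortest-path distance matrix of a weighted network
#'
#' Connection weights are converted to lengths `1/w_ij` (stronger
#' connections are closer), and shortest weighted path lengths are computed
#' by Dijkstra's algorithm from every source. Unreachable pairs get `Inf`,
#' the diagonal is 0. The inverse-length convention is what makes efficiency
#' increase with connection strength.
#'
#' @param G A [weighted_network()] or weight matrix.
#' @return An N x N numeric distance matrix.
#' @export
shortest_path_distances <- function(G) {
  w <- as_weight_matrix(G)
  d <- distances_trusted(w)
  dimnames(d) <- dimnames(w)
  d
}

# Dijkstra distances for an already-validated weight matrix (no checks).
distances_trusted <- function(w) {
  n <- nrow(w)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    d <- matrix(Inf, n, n)
    diag(d) <- 0
    return(d)
  }
  g <- igraph::graph_from_edgelist(idx, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::distances(g, weights = 1 / w[idx], algorithm = "dijkstra")
}

# Global efficiency from a trusted weight matrix. Neighbor subgraphs are
# small, so a dense all-pairs (Floyd-Warshall) pass beats per-subgraph
# Dijkstra setup cost.
efficiency_trusted <- function(w) {
  n <- nrow(w)
  if (n < 2) return(0)
  d <- matrix(Inf, n, n)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], "+")
    lower <- dk < d
    if (any(lower)) d[lower] <- dk[lower]
  }
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Total network strength
#'
#' `S = (1/N) * sum_{i != j} w_ij`, the mean nodal strength (each undirected
#' edge enters the double sum twice). `per = "edge"` instead averages over
#' the K existing edges (sum of weights / K), an alternative reading of
#' "mean of all edge weights"; the nodal form is the default.
#'
#' @param G A [weighted_network()] or weight matrix.
#' @param per Either `"node"` (default) or `"edge"`.
#' @return A nonnegative scalar.
#' @export
total_strength <- function(G, per = c("node", "edge")) {
  per <- match.arg(per)
  G <- if (inherits(G, "weighted_network")) G else weighted_network(G)
  if (per == "node") return(sum(G$weights) / G$N)
  if (G$K == 0) return(0)
  sum(G$weights) / 2 / G$K
}

#' Node strengths and degrees
#'
#' @param G A [weighted_network()] or weight matrix.
#' @return `node_strength`: per-node sum of incident weights;
#'   `node_degree`: per-node count of incident edges.
#' @export
node_strength <- function(G) {
  w <- as_weight_matrix(G)
  colSums(w)
}

#' @rdname node_strength
#' @export
node_degree <- function(G) {
  w <- as_weight_matrix(G)
  colSums(w > 0)
}

#' Weighted clustering coefficient (Onnela triangle intensity)
#'
#' Weights are first scaled by the network's maximum weight so all edge
#' weights lie in \[0, 1\]; the per-node coefficient is the sum of cube-root
#' triangle intensities over unordered neighbor pairs, divided by
#' `k_i (k_i - 1) / 2`. Nodes with fewer than two neighbors get 0.
#'
#' @param G A [weighted_network()] or weight matrix.
#' @return A list with `per_node` (vector of CC_i) and `mean` (network CC).
#' @export
weighted_clustering <- function(G) {
  w <- as_weight_matrix(G)
  n <- nrow(w)
  k <- colSums(w > 0)
  mx <- max(w)
  cc <- numeric(n)
  if (mx > 0) {
    a <- (w / mx)^(1 / 3)
    # diag(a %*% a %*% a) counts each closed neighbor pair twice
    tri <- diag(a %*% a %*% a) / 2
    denom <- k * (k - 1) / 2
    cc <- ifelse(k >= 2, tri / denom, 0)
  }
  names(cc) <- rownames(w)
  list(per_node = cc, mean = mean(cc))
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over ordered node pairs, with
#' disconnected pairs contributing 0: the network's capacity for parallel
#' information transfer.
#'
#' @param G A [weighted_network()] or weight matrix.
#' @param distances Optional precomputed matrix from
#'   [shortest_path_distances()].
#' @return A nonnegative scalar.
#' @export
global_efficiency <- function(G, distances = NULL) {
  if (is.null(distances)) distances <- shortest_path_distances(G)
  n <- nrow(distances)
  if (n < 2) return(0)
  inv <- 1 / distances
  diag(inv) <- 0
  inv[is.infinite(distances)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Characteristic path length (harmonic mean distance)
#'
#' The reciprocal of the average of reciprocal distances, i.e. `1/E_glob`.
#' The harmonic form keeps disconnected node pairs from blowing up the mean.
#'
#' @param G A [weighted_network()] or weight matrix.
#' @param distances Optional precomputed distance matrix.
#' @return A positive scalar; errors when no finite path exists.
#' @export
char_path_length <- function(G, distances = NULL) {
  eg <- global_efficiency(G, distances)
  if (eg <= 0) stop("characteristic path length undefined: no finite paths")
  1 / eg
}

#' Local efficiency
#'
#' Mean, over nodes, of the global efficiency of the subgraph induced on
#' each node's neighbors (the node itself excluded, original weights kept).
#' Quantifies fault tolerance to single-node removal. Nodes with fewer than
#' two neighbors contribute 0.
#'
#' @param G A [weighted_network()] or weight matrix.
#' @return A nonnegative scalar.
#' @export
local_efficiency <- function(G) {
  w <- as_weight_matrix(G)
  n <- nrow(w)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    efficiency_trusted(w[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

#' Nodal (regional) efficiency
#'
#' `E_nodal(i) = (1/(N-1)) * sum_{j != i} 1/d_ij`: the mean inverse
#' shortest-path distance from node i to every other node.
#'
#' @param G A [weighted_network()] or weight matrix.
#' @param distances Optional precomputed distance matrix.
#' @return A named per-node numeric vector.
#' @export
nodal_efficiency <- function(G, distances = NULL) {
  if (is.null(distances)) distances <- shortest_path_distances(G)
  n <- nrow(distances)
  if (n < 2) stop("nodal efficiency requires at least two nodes")
  inv <- 1 / distances
  diag(inv) <- 0
  inv[is.infinite(distances)] <- 0
  rowSums(inv) / (n - 1)
}

#' Identify hub nodes by the one-standard-deviation rule
#'
#' A node is a hub when its value is at least one sample standard deviation
#' (n - 1 denominator) above the mean of all nodes. A degenerate input with
#' zero spread yields no hubs.
#'
#' @param values Per-node numeric vector (nodal efficiency for global hubs,
#'   participation coefficient for connector hubs).
#' @return Integer indices of the hub nodes (named if `values` is named).
#' @export
identify_hubs <- function(values) {
  if (length(values) < 2) stop("need at least two nodes")
  s <- stats::sd(values)
  if (s == 0) return(integer(0))
  which(values >= mean(values) + s)
}

#' All global metrics of one network
#'
#' Convenience wrapper computing strength, clustering, path length, global
#' and local efficiency, and the modularity of the greedy partition, sharing
#' one distance matrix.
#'
#' @param G A [weighted_network()] or weight matrix.
#' @return A one-row data frame with columns `S`, `CC`, `L`, `E_glob`,
#'   `E_loc`, `Q`.
#' @export
global_metrics <- function(G) {
  G <- if (inherits(G, "weighted_network")) G else weighted_network(G)
  d <- shortest_path_distances(G)
  eg <- global_efficiency(G, d)
  part <- greedy_modularity(G)
  data.frame(
    S = total_strength(G),
    CC = weighted_clustering(G)$mean,
    L = if (eg > 0) 1 / eg else NA_real_,
    E_glob = eg,
    E_loc = local_efficiency(G),
    Q = part$Q
  )
}

#' All nodal metrics of one network
#'
#' @param G A [weighted_network()] or weight matrix.
#' @param partition Optional partition (from [greedy_modularity()] or an
#'   assignment vector) used for participation coefficients; computed by
#'   the greedy algorithm when missing.
#' @return A data frame with one row per node: `node`, `degree`, `strength`,
#'   `clustering`, `E_nodal`, `PC`, `module`, `is_hub`, `is_connector`.
#' @export
nodal_metrics <- function(G, partition = NULL) {
  G <- if (inherits(G, "weighted_network")) G else weighted_network(G)
  if (is.null(partition)) partition <- greedy_modularity(G)
  assign <- partition_assignment(partition, G$N)
  en <- nodal_efficiency(G)
  pc <- participation_coefficients(G, assign)
  data.frame(
    node = G$node_labels,
    degree = as.integer(node_degree(G)),
    strength = node_strength(G),
    clustering = weighted_clustering(G)$per_node,
    E_nodal = en,
    PC = pc,
    module = assign,
    is_hub = seq_len(G$N) %in% identify_hubs(en),
    is_connector = seq_len(G$N) %in% connector_hubs(pc),
    row.names = NULL
  )
}
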