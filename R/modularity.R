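#' Weighted Newman modularity of a partition
#'
#' `Q = sum_s [ w_s/W - (W_s/(2W))^2 ]`, where `W` is the total edge weight
#' (each unordered edge counted once), `w_s` the intra-module edge weight of
#' module s and `W_s` the summed strengths of its nodes. Q measures the
#' excess of intra-module weight over the expectation of a strength-matched
#' random network.
#'
#' @param G A [weighted_network()] or weight matrix.
#' @param partition A module assignment: an integer/factor vector over
#'   nodes, or a `network_partition` object.
#' @return The scalar Q.
#' @export
modularity_q <- function(G, partition) {
  w <- as_weight_matrix(G)
  n <- nrow(w)
  assign <- partition_assignment(partition, n)
  W <- sum(w) / 2
  if (W == 0) stop("modularity undefined for a network with zero total weight")
  mods <- sort(unique(assign))
  terms <- vapply(mods, function(s) {
    in_s <- assign == s
    w_s <- sum(w[in_s, in_s]) / 2
    W_s <- sum(w[in_s, ])
    w_s / W - (W_s / (2 * W))^2
  }, numeric(1))
  sum(terms)
}

# Normalize a partition argument to an integer assignment vector of length n.
partition_assignment <- function(partition, n) {
  if (inherits(partition, "network_partition")) partition <- partition$assignment
  assign <- as.integer(as.factor(partition))
  if (length(assign) != n)
    stop("partition must assign every node exactly once")
  assign
}

# Build the full partition object (module sums entering Q) for a graph.
make_partition <- function(G, assign) {
  w <- as_weight_matrix(G)
  assign <- partition_assignment(assign, nrow(w))
  mods <- sort(unique(assign))
  relabel <- match(assign, mods)
  W <- sum(w) / 2
  w_s <- vapply(seq_along(mods), function(s)
    sum(w[relabel == s, relabel == s]) / 2, numeric(1))
  W_s <- vapply(seq_along(mods), function(s)
    sum(w[relabel == s, ]), numeric(1))
  names(relabel) <- rownames(w)
  structure(
    list(assignment = relabel, N_M = length(mods), W = W, w_s = w_s,
         W_s = W_s, Q = modularity_q(w, relabel)),
    class = "network_partition"
  )
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("Partition: %d modules over %d nodes, Q = %.4f\n",
              x$N_M, length(x$assignment), x$Q))
  cat("  module sizes:", paste(tabulate(x$assignment, x$N_M), collapse = ", "),
      "\n")
  invisible(x)
}

#' Module detection by size-normalized greedy agglomeration
#'
#' Starts from singleton modules and repeatedly merges the connected module
#' pair with the largest size-normalized modularity gain
#' `dQ' = dQ / a_s`, where `a_s = W_s/(2W)` of the lower-strength module of
#' the pair. The normalization counteracts the plain greedy algorithm's bias
#' toward balanced module sizes and lets small modules survive next to large
#' ones. Merging continues while connected pairs remain; the partition along
#' the merge path with the largest plain Q is returned. Ties are broken by
#' the lowest (module, module) index pair, so the algorithm is deterministic
#' given the node order.
#'
#' @param G A [weighted_network()] or weight matrix with at least one edge.
#' @return A `network_partition` with elements `assignment` (1-based module
#'   ids), `N_M`, `W`, `w_s`, `W_s` and `Q`.
#' @export
greedy_modularity <- function(G) {
  w <- as_weight_matrix(G)
  n <- nrow(w)
  W2 <- sum(w)                       # 2W
  if (W2 == 0) stop("cannot detect modules in an empty network")

  # e[r,s] = inter-module weight / 2W; a[r] = module strength / 2W
  e <- w / W2
  a <- colSums(e)
  assign <- seq_len(n)               # current module of each node
  alive <- rep(TRUE, n)
  q <- sum(diag(e)) - sum(a^2)       # Q of singleton partition (diag is 0)
  best_q <- q
  best_assign <- assign

  repeat {
    live <- which(alive)
    if (length(live) < 2) break
    el <- e[live, live, drop = FALSE]
    al <- a[live]
    dq <- 2 * (el - outer(al, al))
    conn <- el > 0
    diag(conn) <- FALSE
    conn[lower.tri(conn)] <- FALSE
    if (!any(conn)) break            # disconnected remnants: Q peak passed
    amin <- outer(al, al, pmin)
    gain <- ifelse(conn, dq / amin, -Inf)
    # max normalized gain; ties resolved by lowest (row, col) pair
    mx <- max(gain[conn])
    cand <- which(gain == mx, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    r <- live[cand[1, 1]]
    s <- live[cand[1, 2]]
    # merge s into r
    q <- q + dq[cand[1, 1], cand[1, 2]]
    e[r, ] <- e[r, ] + e[s, ]
    e[, r] <- e[, r] + e[, s]
    # self-weight of the merged module accumulates both selfs plus the link;
    # the row/col additions above already achieve that for e[r, r]
    e[s, ] <- 0
    e[, s] <- 0
    a[r] <- a[r] + a[s]
    a[s] <- 0
    alive[s] <- FALSE
    assign[assign == s] <- r
    if (q > best_q + 1e-12) {
      best_q <- q
      best_assign <- assign
    }
  }
  make_partition(w, best_assign)
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_s (w_is / w_i)^2`, where `w_is` is the weight from node i
#' to module s (the node's own module included) and `w_i` its strength.
#' P is 0 when all of a node's weight stays inside its module and approaches
#' `1 - 1/N_M` when the weight is spread evenly over all modules. Nodes with
#' zero strength get 0.
#'
#' @param G A [weighted_network()] or weight matrix.
#' @param partition Module assignment vector or `network_partition`.
#' @return A named per-node numeric vector.
#' @export
participation_coefficients <- function(G, partition) {
  w <- as_weight_matrix(G)
  n <- nrow(w)
  assign <- partition_assignment(partition, n)
  strength <- colSums(w)
  mods <- sort(unique(assign))
  # w_is: node x module incident-weight matrix
  wis <- vapply(mods, function(s) rowSums(w[, assign == s, drop = FALSE]),
                numeric(n))
  pc <- 1 - rowSums(sweep(wis, 1, pmax(strength, .Machine$double.xmin), "/")^2)
  pc[strength == 0] <- 0
  names(pc) <- rownames(w)
  pc
}

#' Connector (inter-modular) hubs
#'
#' Applies the one-standard-deviation hub rule of [identify_hubs()] to a
#' participation-coefficient vector.
#'
#' @param pc Per-node participation coefficients.
#' @return Integer indices of connector hubs.
#' @export
connector_hubs <- function(pc) identify_hubs(pc)

#' Normalized mutual information between two partitions
#'
#' Standard NMI with the arithmetic-mean entropy normalization; 1 for
#' identical partitions (up to relabeling), 0 for independent ones. Used to
#' score recovery of planted module structure.
#'
#' @param a,b Module assignment vectors (or `network_partition` objects) of
#'   equal length.
#' @return A value in \[0, 1\].
#' @export
partition_nmi <- function(a, b) {
  if (inherits(a, "network_partition")) a <- a$assignment
  if (inherits(b, "network_partition")) b <- b$assignment
  if (length(a) != length(b)) stop("partitions must cover the same nodes")
  n <- length(a)
  joint <- table(a, b) / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  hx <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hy <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
  if (hx == 0 && hy == 0) return(1)
  if (mi <= 0) return(0)
  mi / ((hx + hy) / 2)
}
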