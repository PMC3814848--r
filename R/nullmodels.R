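#' Degree-preserving rewiring (Maslov-Sneppen double-edge swaps)
#'
#' Repeatedly picks two existing edges (a,b) and (c,d) at random and replaces
#' them by (a,d) and (c,b) when neither a self-loop nor a duplicate edge
#' would result. Each edge carries its weight along, so the degree sequence,
#' edge count and the multiset of edge weights (hence total strength) are
#' preserved exactly while the topology is randomized.
#'
#' @param G A [weighted_network()] or weight matrix with at least two edges.
#' @param n_swaps Number of successful swaps to perform (default `10 * K`,
#'   a common mixing heuristic).
#' @param seed Optional integer seed for reproducibility.
#' @return A [weighted_network()]; if fewer than `n_swaps` swaps succeed
#'   within `100 * n_swaps` proposals, the current state is returned with
#'   attribute `"incomplete" = TRUE` and a warning.
#' @export
rewire_maslov_sneppen <- function(G, n_swaps = NULL, seed = NULL) {
  G <- if (inherits(G, "weighted_network")) G else weighted_network(G)
  if (G$K < 2) stop("rewiring requires at least two edges")
  if (is.null(n_swaps)) n_swaps <- 10L * G$K
  if (!is.null(seed)) set.seed(seed)
  w <- G$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  ei <- idx[, 1]
  ej <- idx[, 2]
  ew <- w[idx]
  m <- length(ew)
  adj <- w > 0
  done <- 0L
  attempts <- 0L
  cap <- 100L * n_swaps
  block <- 2048L
  while (done < n_swaps && attempts < cap) {
    # draw proposals in blocks to keep RNG overhead off the inner loop
    nb <- min(block, cap - attempts)
    p1 <- sample.int(m, nb, replace = TRUE)
    p2 <- sample.int(m, nb, replace = TRUE)
    flip <- stats::runif(nb) < 0.5
    for (t in seq_len(nb)) {
      attempts <- attempts + 1L
      e1 <- p1[t]; e2 <- p2[t]
      if (e1 == e2) next
      a <- ei[e1]; b <- ej[e1]; c <- ei[e2]; d <- ej[e2]
      # randomize the orientation of the second edge
      if (flip[t]) { tmp <- c; c <- d; d <- tmp }
      # proposal: (a,b),(c,d) -> (a,d),(c,b)
      if (a == d || c == b || a == c || b == d) next
      if (adj[a, d] || adj[c, b]) next
      adj[a, b] <- FALSE; adj[b, a] <- FALSE
      adj[c, d] <- FALSE; adj[d, c] <- FALSE
      adj[a, d] <- TRUE; adj[d, a] <- TRUE
      adj[c, b] <- TRUE; adj[b, c] <- TRUE
      ej[e1] <- d                     # weight ew[e1] rides from (a,b) to (a,d)
      ei[e2] <- c; ej[e2] <- b
      done <- done + 1L
      if (done == n_swaps) break
    }
  }
  out <- matrix(0, G$N, G$N)
  out[cbind(ei, ej)] <- ew
  out[cbind(ej, ei)] <- ew
  res <- weighted_network(out, node_labels = G$node_labels)
  if (done < n_swaps) {
    warning(sprintf("rewiring stalled after %d of %d swaps", done, n_swaps))
    attr(res, "incomplete") <- TRUE
  }
  res
}

#' Small-worldness against a matched random-network ensemble
#'
#' Generates `n_networks` independent degree-preserving rewired versions of
#' the input, computes the mean clustering coefficient and characteristic
#' path length over the ensemble, and returns the ratios
#' `gamma = CC/CC_rand`, `lambda = L/L_rand` and their quotient
#' `sigma = gamma/lambda`. A network is called small-world when `gamma > 1`
#' with `lambda ~ 1`, i.e. `sigma` clearly above 1.
#'
#' @param G A [weighted_network()] or weight matrix with `E_glob > 0`.
#' @param n_networks Ensemble size (default 1000).
#' @param seed Integer seed; each null uses its own derived stream.
#' @param n_swaps_per_edge Successful swaps per edge for each null
#'   (default 10).
#' @return A list with `gamma`, `lambda`, `sigma`, `CC`, `L`, `CC_rand`,
#'   `L_rand`, `n_networks` and `seed`.
#' @export
small_worldness <- function(G, n_networks = 1000, seed = NULL,
                            n_swaps_per_edge = 10) {
  G <- if (inherits(G, "weighted_network")) G else weighted_network(G)
  cc <- weighted_clustering(G)$mean
  eg <- global_efficiency(G)
  if (eg <= 0) stop("small-worldness requires a network with finite paths")
  L <- 1 / eg
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  n_swaps <- as.integer(n_swaps_per_edge * G$K)
  cc_r <- numeric(n_networks)
  l_r <- numeric(n_networks)
  for (b in seq_len(n_networks)) {
    R <- rewire_maslov_sneppen(G, n_swaps = n_swaps,
                               seed = (seed + b - 1) %% .Machine$integer.max)
    cc_r[b] <- weighted_clustering(R)$mean
    eg_r <- global_efficiency(R)
    l_r[b] <- if (eg_r > 0) 1 / eg_r else NA_real_
  }
  CC_rand <- mean(cc_r)
  L_rand <- mean(l_r, na.rm = TRUE)
  if (!is.finite(CC_rand) || CC_rand <= 0)
    stop("degenerate null ensemble: mean random clustering is zero")
  gamma <- cc / CC_rand
  lambda <- L / L_rand
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       CC = cc, L = L, CC_rand = CC_rand, L_rand = L_rand,
       CC_rand_sd = stats::sd(cc_r), L_rand_sd = stats::sd(l_r, na.rm = TRUE),
       n_networks = n_networks, seed = seed)
}
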