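# Small graph fixtures, built in code.

sym_from_edges <- function(n, edges, weights = 1) {
  w <- matrix(0, n, n)
  weights <- rep_len(weights, length(edges))
  for (k in seq_along(edges)) {
    e <- edges[[k]]
    w[e[1], e[2]] <- w[e[2], e[1]] <- weights[k]
  }
  w
}

unit_triangle <- function()
  sym_from_edges(3, list(c(1, 2), c(2, 3), c(1, 3)))

unit_path3 <- function()
  sym_from_edges(3, list(c(1, 2), c(2, 3)))

unit_k4 <- function() {
  w <- matrix(1, 4, 4)
  diag(w) <- 0
  w
}

unit_star <- function(n = 5)
  sym_from_edges(n, lapply(2:n, function(i) c(1, i)))

two_triangles <- function()
  sym_from_edges(6, list(c(1, 2), c(2, 3), c(1, 3),
                         c(4, 5), c(5, 6), c(4, 6)))

# Random connected-ish weighted graph with uniform weights.
rand_weighted <- function(n, p = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(0, n, n)
  up <- which(upper.tri(w))
  on <- up[stats::runif(length(up)) < p]
  w[on] <- stats::runif(length(on), 0.1, 2)
  w + t(w)
}

# Planted-partition graph with unit weights.
planted_graph <- function(assign, p_in, p_out, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(assign)
  P <- ifelse(outer(assign, assign, "=="), p_in, p_out)
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  w[up] <- stats::rbinom(sum(up), 1, P[up])
  w + t(w)
}

# Watts-Strogatz-style ring lattice with unit weights.
ring_lattice_graph <- function(n = 78, nei = 4, p_rewire = 0.1, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_smallworld(1, n, nei, p_rewire)
  w <- as.matrix(igraph::as_adjacency_matrix(g))
  w[w > 1] <- 1
  diag(w) <- 0
  w
}

# A tiny synthetic cohort spec for fast pipeline tests. Group size must stay
# large enough for the Bonferroni sign test to retain edges at all
# (0.5^n <= alpha / n_pairs needs n >= 14 at 30 regions).
small_cohort_spec <- function(seed = 1, ...) {
  cohort_spec(n_groups = 3, n_per_group = 15, n_regions = 30, n_modules = 3,
              seed = seed, ...)
}
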