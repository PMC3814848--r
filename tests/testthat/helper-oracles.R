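# Independent brute-force oracles used to cross-check the implementation.

# All-pairs shortest paths by Floyd-Warshall on inverse-weight lengths.
fw_distances_oracle <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Global/nodal efficiency by direct summation over an oracle distance matrix.
eff_from_distances <- function(d) {
  n <- nrow(d)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  list(e_glob = sum(inv) / (n * (n - 1)), e_nodal = rowSums(inv) / (n - 1))
}

# All set partitions of 1..n (Bell-number enumeration, recursive).
all_partitions <- function(n) {
  if (n == 1) return(list(c(1L)))
  out <- list()
  for (p in all_partitions(n - 1)) {
    m <- max(p)
    for (s in seq_len(m + 1)) out[[length(out) + 1]] <- c(p, s)
  }
  out
}

# Exhaustive maximum modularity over every partition.
exhaustive_max_q <- function(w) {
  parts <- all_partitions(nrow(w))
  qs <- vapply(parts, function(p) modularity_q(w, p), numeric(1))
  list(q = max(qs), partition = parts[[which.max(qs)]])
}

# Benjamini-Hochberg step-up, written out literally.
bh_oracle <- function(p, q) {
  m <- length(p)
  if (m == 0) return(logical(0))
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= seq_len(m) * q / m)
  if (length(below) == 0) return(rep(FALSE, m))
  p[seq_len(m)] <= ps[max(below)]
}

# One-tailed exact binomial upper tail by direct summation.
binom_tail_oracle <- function(k, n) sum(choose(n, k:n)) / 2^n
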